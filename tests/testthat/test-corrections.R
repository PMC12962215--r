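test_that("center phases reproduce the direction-odd forward model", {
  mod <- imperfection_model(phase_coeffs = c(1, 0, 0))
  kd <- small_ball_kspace(n_spokes = 300, samples = 25, model = mod)
  tab <- extract_center_phase(kd)
  expect_equal(tab$phase, sin(tab$theta) * cos(tab$phi), tolerance = 1e-8)
  # a spoke and its exact antipode carry opposite phases by construction
  expect_equal(sin(tab$theta) * cos(tab$phi),
               -sin(pi - tab$theta) * cos(tab$phi + pi), tolerance = 1e-12)
  # zero-magnitude center flags NA instead of zero phase
  kd0 <- kd
  kd0$samples[3, kd0$center_index, 1] <- 0
  expect_true(is.na(extract_center_phase(kd0)$phase[3]))
})

test_that("hemisphere split partitions the data and refuses one hemisphere", {
  cfg <- trajectory_config(200, 10, design = "pole_to_pole",
                           samples_per_spoke = 9)
  kd <- simulate_acquisition(ball_phantom(5), build_spoke_set(cfg))
  halves <- split_hemispheres(kd)
  expect_setequal(c(halves$upper$spokes$n, halves$lower$spokes$n), 1:200)
  expect_length(intersect(halves$upper$spokes$n, halves$lower$spokes$n), 0)
  expect_lte(abs(nrow(halves$upper$spokes) - 100), 1)
  orig <- build_spoke_set(trajectory_config(100, 10, design = "original"))
  expect_error(split_hemispheres(orig), "single-hemisphere")
})

test_that("opposing-spoke search matches exhaustive search exactly", {
  for (des in c("pole_to_pole", "continuous")) {
    cfg <- trajectory_config(200, 10, design = des, samples_per_spoke = 5)
    ss <- build_spoke_set(cfg)
    fast <- find_opposing(ss)
    ref <- brute_force_opposing(ss)
    expect_identical(fast$partner, ref$partner)
    expect_equal(fast$gap, ref$gap, tolerance = 1e-12)
    expect_true(all(fast$gap >= 0 & fast$gap <= pi))
    # partners are always in the opposite start hemisphere
    hemi <- ss$hemisphere[match(fast$partner, ss$n)]
    expect_true(all(hemi != ss$hemisphere))
  }
  # exact antipodal pair is mutual with zero gap
  two <- build_spoke_set(trajectory_config(4, 2, 2, design = "pole_to_pole",
                                           samples_per_spoke = 3))
  p <- find_opposing(two)
  expect_true(all(p$gap <= pi / 2))
  expect_error(find_opposing(build_spoke_set(
    trajectory_config(20, 2, design = "original"))), "opposite hemisphere")
})

test_that("mean opposing gap shrinks with spoke count", {
  g <- sapply(c(200, 2000), function(N) {
    ss <- build_spoke_set(trajectory_config(N, 10, design = "pole_to_pole",
                                            samples_per_spoke = 3))
    mean(find_opposing(ss)$gap)
  })
  expect_lt(g[2], g[1])
  # antipodal coverage: mean gap below twice the mean angular spacing
  ss <- build_spoke_set(trajectory_config(2000, 10, design = "pole_to_pole",
                                          samples_per_spoke = 3))
  spacing <- sqrt(4 * pi / 2000)
  expect_lt(mean(find_opposing(ss)$gap), 2 * spacing)
})

test_that("opposing-phase correction preserves magnitudes and cancels odd phase", {
  mod <- imperfection_model(phase_coeffs = c(0, 0, 0.8))
  kd <- small_ball_kspace(n_spokes = 400, samples = 25, model = mod)
  pairs <- find_opposing(kd)
  phases <- extract_center_phase(kd)
  corr <- opposing_phase_correction(kd, pairs, phases)
  expect_equal(Mod(corr$samples), Mod(kd$samples), tolerance = 1e-14)
  # corrected center phases collapse toward zero: pair sums vanish and the
  # per-spoke residual is bounded by the pairing gap
  tab2 <- extract_center_phase(corr)
  p <- tab2$phase; names(p) <- tab2$n
  sums <- p[as.character(pairs$n)] + p[as.character(pairs$partner)]
  sums <- atan2(sin(sums), cos(sums))
  # residual is bounded by the error coefficient times the pairing gaps
  expect_lt(median(abs(sums)), 4 * 0.8 * median(pairs$gap))
  expect_lt(median(abs(tab2$phase)), median(abs(phases$phase)) / 5)
  # all partner phases zero: correction is the identity
  phases0 <- phases; phases0$phase <- 0
  ident <- opposing_phase_correction(kd, pairs, phases0)
  expect_equal(ident$samples, kd$samples, tolerance = 1e-14)
  # the literal printed sign doubles instead of cancelling the odd phase
  lit <- opposing_phase_correction(kd, pairs, phases, convention = "literal")
  tabl <- extract_center_phase(lit)
  expect_gt(median(abs(tabl$phase)), 1.5 * median(abs(phases$phase)))
})

test_that("hemisphere-subset correction restores the clean-subset image", {
  mod <- imperfection_model(phase_coeffs = c(0, 0, 1))
  cfg <- trajectory_config(2000, 10, design = "pole_to_pole",
                           samples_per_spoke = 97)
  ss <- build_spoke_set(cfg)
  ph <- ball_phantom(radius = 15)
  kd <- simulate_acquisition(ph, ss, mod)
  rc <- recon_config(48)
  pairs <- find_opposing(kd)
  phases <- extract_center_phase(kd)
  halves <- split_hemispheres(kd)
  am_unc <- artifact_metric(recon_radial(halves$upper, rc), ph)
  corr <- opposing_phase_correction(halves$upper, pairs, phases)
  am_cor <- artifact_metric(recon_radial(corr, rc), ph)
  # artifact drops substantially ...
  expect_gt(am_unc$artifact_energy / am_cor$artifact_energy, 2)
  # ... all the way back to the clean-subset baseline
  clean <- split_hemispheres(simulate_acquisition(ph, ss))$upper
  am_clean <- artifact_metric(recon_radial(clean, rc), ph)
  expect_equal(am_cor$artifact_energy, am_clean$artifact_energy,
               tolerance = 0.05)
  # subset-only reconstruction is worse than the full corrupted set
  am_full <- artifact_metric(recon_radial(kd, rc), ph)
  expect_gt(am_unc$artifact_energy, am_full$artifact_energy)
})

test_that("gradient-delay correction recovers injected delays", {
  ph <- ball_phantom(radius = 12)
  cfg <- trajectory_config(600, 10, design = "pole_to_pole",
                           samples_per_spoke = 49)
  ss <- build_spoke_set(cfg)
  # zero-delay data: fitted slope and intercept are numerically zero
  kd0 <- simulate_acquisition(ph, ss)
  r0 <- gradient_delay_correction(kd0)
  expect_lt(max(abs(r0$fits$a), na.rm = TRUE), 1e-3)
  expect_lt(rel_l2(r0$kdata$samples, kd0$samples), 1e-6)
  # 0.5-sample isotropic delay is recovered within 0.05 samples
  mod <- imperfection_model(delays = c(0.5, 0.5, 0.5))
  kd <- simulate_acquisition(ph, ss, mod)
  res <- gradient_delay_correction(kd)
  expect_lt(abs(median(res$fits$delay_samples, na.rm = TRUE) - 0.5), 0.05)
  # center phases of opposing pairs agree after correction
  tab <- extract_center_phase(res$kdata)
  p <- tab$phase; names(p) <- tab$n
  pairs <- find_opposing(res$kdata)
  dd <- p[as.character(pairs$n)] - p[as.character(pairs$partner)]
  dd <- atan2(sin(dd), cos(dd))
  expect_lt(median(abs(dd)), 0.02)
  # short readouts are refused
  kds <- small_ball_kspace(n_spokes = 20, samples = 9)
  expect_error(gradient_delay_correction(kds), "16 readout samples")
})
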