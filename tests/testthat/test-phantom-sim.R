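test_that("analytic ball transform matches DC value, symmetry and a DFT oracle", {
  comp <- list(center = c(0, 0, 0), radius = 1, amplitude = 1 + 0i)
  expect_equal(Re(analytic_ball_transform(comp, c(0, 0, 0))), 4 * pi / 3,
               tolerance = 1e-12)
  # Hermitian symmetry of a real, centered phantom
  set.seed(3)
  ks <- matrix(runif(60, -0.4, 0.4), ncol = 3)
  comp2 <- list(center = c(0, 0, 0), radius = 6, amplitude = 1 + 0i)
  expect_equal(analytic_ball_transform(comp2, -ks),
               Conj(analytic_ball_transform(comp2, ks)), tolerance = 1e-12)
  # brute-force DFT oracle: anti-aliased (partial-volume) rasterization of
  # the ball on a 64^3 grid, compared at low and mid frequencies
  m <- 64L; R <- 8; ctr <- c(3, -2, 1)
  ax <- seq_len(m) - m / 2 - 1
  A <- array(rep(ax, times = m^2), dim = rep(m, 3))
  X <- A; Y <- aperm(A, c(2, 1, 3)); Z <- aperm(A, c(3, 2, 1))
  r <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
  vol <- array(pmin(1, pmax(0, R + 0.5 - r)), dim = rep(m, 3))
  ksp <- phyllotaxr:::fftshift3(fft(phyllotaxr:::fftshift3(vol)))
  axk <- (seq_len(m) - m / 2 - 1) / m     # cycles/voxel of the DFT grid
  grid <- as.matrix(expand.grid(kx = axk, ky = axk, kz = axk))
  sel <- sqrt(rowSums(grid^2)) <= 0.25
  ana <- analytic_ball_transform(list(center = ctr, radius = R,
                                      amplitude = 1 + 0i), grid[sel, ])
  expect_lt(rel_l2(ana, as.vector(ksp)[sel]), 0.02)
})

test_that("spoke corruption is odd in direction and reduces correctly", {
  cfg <- trajectory_config(8, 2, design = "pole_to_pole",
                           samples_per_spoke = 5,
                           si_spoke_mode = "replace_with_z")
  ss <- build_spoke_set(cfg)
  ident <- corrupt_spokes(ss, imperfection_model())
  expect_true(all(ident$shift == 0) && all(ident$phase == 0))
  # zeroth-order phase is c . d, odd under d -> -d
  mod <- imperfection_model(phase_coeffs = c(0.3, -0.2, 1))
  co <- corrupt_spokes(ss, mod)
  d <- spoke_directions(ss)
  expect_equal(co$phase, as.vector(d %*% c(0.3, -0.2, 1)))
  z_spoke <- which(ss$dz == 1)[1]
  expect_equal(co$phase[z_spoke], 1)
  # isotropic delay: pure along-readout shift of t samples, no perpendicular
  mod_t <- imperfection_model(delays = c(0.7, 0.7, 0.7))
  ct <- corrupt_spokes(ss, mod_t)
  dk <- 2 * 0.5 / (5 - 1)
  expect_equal(ct$shift, 0.7 * dk * d, tolerance = 1e-12)
  perp <- ct$shift - rowSums(ct$shift * d) * d
  expect_lt(max(abs(perp)), 1e-14)
})

test_that("identity model reproduces the clean simulation bit-exactly", {
  kd1 <- small_ball_kspace(n_spokes = 100)
  kd2 <- small_ball_kspace(n_spokes = 100,
                           model = imperfection_model(c(0, 0, 0), c(0, 0, 0), 0, 0))
  expect_identical(kd1$samples, kd2$samples)
  expect_identical(kd1$nominal_coords, kd1$effective_coords)
})

test_that("noise scaling and seeding behave as declared", {
  ph <- ball_phantom(radius = 7)
  cfg <- trajectory_config(200, 4, design = "pole_to_pole",
                           samples_per_spoke = 51)
  ss <- build_spoke_set(cfg)
  model <- imperfection_model(noise_sigma = 0.02)
  kn <- simulate_acquisition(ph, ss, model, seed = 11)
  k0 <- simulate_acquisition(ph, ss, seed = 11)
  dv <- as.vector(kn$samples - k0$samples)   # > 10^4 samples
  sig <- 0.02 * Mod(phantom_kspace(ph, c(0, 0, 0)))
  expect_equal(var(Re(dv)) + var(Im(dv)), sig^2, tolerance = 0.05)
  expect_identical(kn$samples,
                   simulate_acquisition(ph, ss, model, seed = 11)$samples)
  expect_false(identical(kn$samples,
                         simulate_acquisition(ph, ss, model, seed = 12)$samples))
})

test_that("clean centered real phantom has zero center-sample phase", {
  kd <- small_ball_kspace(n_spokes = 60, samples = 25)
  ctr <- kd$samples[, kd$center_index, 1]
  expect_lt(max(abs(Arg(ctr))), 1e-10)
})

test_that("multi-coil forward transform agrees with the analytic path", {
  ph <- ball_phantom(radius = 10)
  cfg <- trajectory_config(400, 8, design = "pole_to_pole",
                           samples_per_spoke = 65)
  ss <- build_spoke_set(cfg)
  flat <- array(1 + 0i, dim = c(32, 32, 32, 1))
  kd_grid <- simulate_acquisition(ph, ss, coil_profiles = flat)
  kd_ana <- simulate_acquisition(ph, ss)
  # rasterization + gridding vs exact analytic sampling
  expect_lt(rel_l2(kd_grid$samples, kd_ana$samples), 0.02)
})

test_that("bSSFP contrast weights trace the tissue ellipse", {
  ph <- system_phantom(t1 = c(800, 800), t2 = c(90, 90), bath_radius = 0)
  sp <- sequence_params(5, 2.5, 20, seq(0, 340, by = 20))
  # identical tissues get identical amplitudes; zero PD gives zero
  w <- bssfp_contrast_weights(ph, sp, 100)
  expect_equal(w[1], w[2])
  ph0 <- system_phantom(t1 = 800, t2 = 90, n_vials = 1, bath_radius = 0)
  ph0$compartments[[1]]$tissue$proton_density <- 0
  expect_equal(bssfp_contrast_weights(ph0, sp, 100), as.complex(0))
  # across increments the amplitudes lie on the model profile exactly
  amps <- sapply(sp$rf_phase_increments,
                 function(i) bssfp_contrast_weights(ph, sp, i)[1])
  prof <- bssfp_profile(list(T1 = 800, T2 = 90, off_resonance = 0,
                             proton_density = 1), sp)$signal
  expect_lt(max(Mod(amps - prof)), 1e-12)
  # amplitude-only phantom refuses tissue weighting
  expect_error(bssfp_contrast_weights(ball_phantom(), sp, 0), "tissue")
})

test_that("phantom validation enforces tissue consistency", {
  expect_error(phantom_spec(list(
    list(center = c(0, 0, 0), radius = 5, amplitude = 1),
    list(center = c(1, 0, 0), radius = 3,
         tissue = list(T1 = 1000, T2 = 100)))), "all compartments")
  expect_error(phantom_spec(list(
    list(center = c(0, 0, 0), radius = 4,
         tissue = list(T1 = 100, T2 = 900)))), "T1 >= T2")
  expect_error(phantom_spec(list(list(center = c(0, 0), radius = 1))))
})
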