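test_that("azimuthal angle follows the golden-angle progression", {
  cfg <- trajectory_config(100, 10)
  expect_equal(azimuthal_angle(1, cfg), 2.39996, tolerance = 1e-5)
  expect_equal((azimuthal_angle(3, cfg) + 2 * pi) %% (2 * pi),
               (3 * 2.3999632297) %% (2 * pi), tolerance = 1e-6)
  # consecutive increment is the golden angle, 137.51 degrees
  inc <- diff(azimuthal_angle(1:50, cfg)) %% (2 * pi)
  expect_true(all(abs(inc - golden_angle()) < 1e-12))
  expect_equal(golden_angle() * 180 / pi, 137.5077641, tolerance = 1e-6)
  # zero-increment configuration collapses all azimuths
  cfg0 <- trajectory_config(10, 2, golden_angle = 1e-12)
  expect_true(all(azimuthal_angle(1:10, cfg0) < 1e-10))
  expect_error(azimuthal_angle(0, cfg), "out of range")
  expect_error(azimuthal_angle(101, cfg), "out of range")
})

test_that("polar schedules hit their segment boundaries and stay monotone", {
  N <- 1200
  expect_equal(polar_angle_original(N, N), pi / 2)
  expect_equal(polar_angle_pole_to_pole(N / 2, N), pi / 2)
  expect_equal(polar_angle_pole_to_pole(N, N), pi)
  expect_equal(polar_angle_continuous(N / 4, N), pi / 2)
  expect_equal(polar_angle_continuous(N / 2, N), pi)
  expect_equal(polar_angle_continuous(3 * N / 4, N), 3 * pi / 2)
  expect_equal(polar_angle_continuous(N, N), 2 * pi)
  for (f in list(polar_angle_original, polar_angle_pole_to_pole,
                 polar_angle_continuous))
    expect_true(all(diff(f(1:N, N)) > 0))
  # equal-area law near the pole: theta ~ sqrt(n/N)
  expect_equal(polar_angle_original(1, 17800), (pi / 2) * sqrt(1 / 17800))
  expect_error(polar_angle_pole_to_pole(1, 11), "even N")
  expect_error(polar_angle_continuous(1, 10), "divisible by 4")
})

test_that("interleave ordering is the bijection n = k + (j-1) K", {
  cfg <- trajectory_config(17800, 89, 200)
  expect_identical(interleave_order(1, 1, cfg), 1L)
  expect_identical(interleave_order(2, 3, cfg), 92L)
  g <- expand.grid(j = 1:200, k = 1:89)
  n <- interleave_order(g$j, g$k, cfg)
  expect_identical(sort(n), 1:17800)
  set.seed(42)
  for (i in 1:5) {
    K <- sample(2:12, 1); J <- sample(2:30, 1)
    cfgr <- trajectory_config(J * K, K, J, golden_angle = runif(1, 0.1, 6))
    gr <- expand.grid(j = seq_len(J), k = seq_len(K))
    expect_identical(sort(interleave_order(gr$j, gr$k, cfgr)),
                     seq_len(J * K))
  }
  expect_error(interleave_order(0, 1, cfg), "out of range")
  expect_error(interleave_order(1, 90, cfg), "out of range")
})

test_that("spoke directions are unit vectors with the continuous wrap", {
  expect_equal(spoke_direction(0, 1.3)[1, ], c(x = 0, y = 0, z = 1))
  expect_equal(spoke_direction(pi, 0.4)[1, ], c(x = 0, y = 0, z = -1),
               tolerance = 1e-12)
  expect_equal(spoke_direction(3 * pi / 2, 0)[1, ], c(x = -1, y = 0, z = 0),
               tolerance = 1e-12)
  # theta in (pi, 2 pi) equals polar 2 pi - theta with azimuth phi + pi
  th <- 4.1; phi <- 0.7
  expect_equal(spoke_direction(th, phi), spoke_direction(2 * pi - th, phi + pi),
               tolerance = 1e-12)
})

test_that("build_spoke_set fulfils hemisphere and norm invariants", {
  for (des in c("original", "pole_to_pole", "continuous")) {
    cfg <- trajectory_config(1780, 89, 20, design = des)
    ss <- build_spoke_set(cfg)
    expect_identical(sort(ss$n), 1:1780)
    d <- spoke_directions(ss)
    expect_lt(max(abs(sqrt(rowSums(d^2)) - 1)), 1e-12)
    if (des == "original") {
      expect_true(all(ss$hemisphere == "upper"))
      expect_true(all(ss$dz >= 0))
    } else {
      counts <- table(ss$hemisphere)
      expect_lte(abs(counts[["upper"]] - counts[["lower"]]), 1)
    }
    expect_identical(which(ss$is_si_spoke), which(ss$j == 1L))
  }
  # small pole-to-pole enumeration: half the starts in each hemisphere
  ss8 <- build_spoke_set(trajectory_config(8, 2, design = "pole_to_pole"))
  expect_identical(unname(table(ss8$hemisphere)["upper"]), 4L)
})

test_that("SI-spoke replacement overwrites the j = 1 direction with +z", {
  cfg <- trajectory_config(200, 10, design = "original",
                           si_spoke_mode = "replace_with_z")
  ss <- build_spoke_set(cfg)
  si <- ss[ss$is_si_spoke, ]
  expect_true(all(si$dz == 1))
  expect_true(all(abs(si$dx) < 1e-15 & abs(si$dy) < 1e-15))
  # formula mode leaves them on the schedule
  ss2 <- build_spoke_set(trajectory_config(200, 10, design = "original"))
  expect_false(all(ss2$dz[ss2$is_si_spoke] == 1))
})

test_that("sample positions run from +k_max to -k_max through the origin", {
  cfg <- trajectory_config(8, 2, design = "pole_to_pole",
                           samples_per_spoke = 3, si_spoke_mode = "replace_with_z")
  ss <- build_spoke_set(cfg)
  pos <- sample_positions(ss)
  expect_equal(pos[1, , ], rbind(c(0, 0, 0.5), c(0, 0, 0), c(0, 0, -0.5)))
  expect_identical(center_sample_index(3), 2L)
  expect_identical(center_sample_index(49), 25L)
  expect_identical(center_sample_index(4), 3L)
  cfg2 <- trajectory_config(40, 4, samples_per_spoke = 9)
  pos2 <- sample_positions(build_spoke_set(cfg2))
  r <- sqrt(pos2[, , 1]^2 + pos2[, , 2]^2 + pos2[, , 3]^2)
  expect_equal(min(r), 0)
  expect_equal(max(r), 0.5)
})

test_that("trajectory CSV export round-trips", {
  cfg <- trajectory_config(60, 6, design = "continuous", samples_per_spoke = 9)
  ss <- build_spoke_set(cfg)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(ss, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$theta, ss$theta, tolerance = 1e-12)
  expect_equal(spoke_directions(back), spoke_directions(ss), tolerance = 1e-12)
  expect_identical(attr(back, "cfg")$design, "continuous")
  unlink(c(f, paste0(f, ".json")))
})

test_that("trajectory configuration is validated", {
  expect_error(trajectory_config(10, 3), "must equal")
  expect_error(trajectory_config(10, 5, golden_angle = 7), "golden_angle")
  expect_error(trajectory_config(10, 5, samples_per_spoke = 2), "samples_per_spoke")
  expect_error(trajectory_config(10, 2, design = "pole_to_pole"), NA)
  expect_error(trajectory_config(15, 5, design = "pole_to_pole"), "even")
  expect_error(trajectory_config(14, 7, design = "continuous"), "divisible by 4")
})
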