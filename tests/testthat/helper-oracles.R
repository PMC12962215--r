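# Independent oracles and small fixtures used across the suite.

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# Brute-force adjoint non-uniform DFT: img(x) = sum_j w_j s_j e^{+2i pi k_j.x}
# evaluated at the voxel offsets of an m^3 image, chunked to bound memory.
naive_adjoint_nudft <- function(kdata, weights, m, chunk = 600L) {
  ax <- seq_len(m) - m / 2 - 1
  vox <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  co <- matrix(kdata$nominal_coords, ncol = 3)
  vals <- as.vector(kdata$samples[, , 1]) * as.vector(weights)
  out <- complex(length.out = nrow(vox))
  for (i0 in seq(1, length(vals), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(vals))
    out <- out + exp(2i * pi * (vox %*% t(co[ii, , drop = FALSE]))) %*% vals[ii]
  }
  array(out, dim = rep(m, 3))
}

# Iterative Bloch steady-state simulation of phase-cycled bSSFP: hard RF
# pulses with linearly incrementing phase, relaxation + precession over TR,
# sampling at TE with receiver demodulation at the exciting pulse's phase.
# Rotation handedness is fixed to the package's documented conventions
# (increment subtracts from the off-resonance cycle; receiver constant i).
bloch_bssfp_oracle <- function(T1, T2, df, pd, TR, TE, flip, dphi_deg,
                               n_iter = 8000L) {
  al <- flip * pi / 180
  dphi <- dphi_deg * pi / 180
  E1 <- exp(-TR / T1); E2 <- exp(-TR / T2)
  th0 <- 2 * pi * df * TR / 1000
  rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  relax <- diag(c(E2, E2, E1))
  M <- c(0, 0, pd); phase <- 0
  for (n in seq_len(n_iter)) {
    phase <- phase + dphi
    M <- rot_z(-phase) %*% rot_x(al) %*% rot_z(phase) %*% M
    M <- rot_z(-th0) %*% relax %*% M + c(0, 0, pd * (1 - E1))
  }
  phase <- phase + dphi
  M <- rot_z(-phase) %*% rot_x(al) %*% rot_z(phase) %*% M
  Mte <- rot_z(2 * pi * df * TE / 1000) %*%
    diag(c(exp(-TE / T2), exp(-TE / T2), exp(-TE / T1))) %*% M
  1i * complex(real = Mte[1], imaginary = Mte[2]) * exp(-1i * phase)
}

# Small pole-to-pole acquisition of a centered ball, reused by several files.
small_ball_kspace <- function(n_spokes = 500, design = "pole_to_pole",
                              samples = 25, model = imperfection_model(),
                              radius = 7, seed = 1) {
  K <- if (n_spokes %% 10 == 0) 10L else if (n_spokes %% 4 == 0) 4L else 1L
  cfg <- trajectory_config(n_spokes, K, design = design,
                           samples_per_spoke = samples)
  ss <- build_spoke_set(cfg)
  simulate_acquisition(ball_phantom(radius = radius), ss, model, seed = seed)
}

# Exhaustive reference for the opposing-spoke search (plain double loop).
brute_force_opposing <- function(spokes) {
  d <- spoke_directions(spokes)
  up <- spokes$hemisphere == "upper"
  partner <- integer(nrow(spokes)); gap <- numeric(nrow(spokes))
  for (i in seq_len(nrow(spokes))) {
    cand <- which(up != up[i])
    best <- Inf; bj <- NA_integer_
    for (j in cand) {
      ang <- acos(min(1, max(-1, -sum(d[i, ] * d[j, ]))))
      if (ang < best - 1e-15 ||
          (abs(ang - best) <= 1e-15 && spokes$n[j] < spokes$n[bj])) {
        best <- ang; bj <- j
      }
    }
    partner[i] <- spokes$n[bj]; gap[i] <- best
  }
  data.frame(n = spokes$n, partner = partner, gap = gap)
}
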