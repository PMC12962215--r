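#' Parametric gradient-imperfection model
#'
#' A deliberately minimal forward model of the scanner imperfections that
#' corrupt 3D radial acquisitions:
#' \describe{
#'   \item{zeroth-order phase}{a spatially constant phase offset, odd in
#'     the spoke direction d: `phase = c . d` with per-axis coefficients
#'     `phase_coeffs = (cx, cy, cz)` in radians per unit
#'     direction-component (the B0 eddy-current term).}
#'   \item{gradient delays}{per-axis timing offsets `delays = (tx, ty,
#'     tz)` plus a `global_delay`, in readout-sample units, which shift
#'     the effectively traversed k-space positions along (and, for
#'     anisotropic delays, across) the readout line.}
#'   \item{noise}{complex circular Gaussian noise with standard deviation
#'     `noise_sigma` relative to the k-space-center magnitude.}
#' }
#' All parameters zero gives the identity corruption.
#'
#' @param phase_coeffs Numeric length 3, radians per direction component.
#' @param delays Numeric length 3, readout-sample units per axis.
#' @param global_delay Scalar delay in readout-sample units.
#' @param noise_sigma Relative complex-Gaussian noise level, >= 0.
#' @return An object of class `imperfection_model`.
#' @export
imperfection_model <- function(phase_coeffs = c(0, 0, 0),
                               delays = c(0, 0, 0),
                               global_delay = 0,
                               noise_sigma = 0) {
  stopifnot(length(phase_coeffs) == 3L, length(delays) == 3L,
            all(is.finite(c(phase_coeffs, delays, global_delay, noise_sigma))),
            noise_sigma >= 0)
  structure(list(phase_coeffs = as.numeric(phase_coeffs),
                 delays = as.numeric(delays),
                 global_delay = as.numeric(global_delay),
                 noise_sigma = as.numeric(noise_sigma)),
            class = "imperfection_model")
}

#' @export
print.imperfection_model <- function(x, ...) {
  cat(sprintf("<imperfection_model> phase c = (%g, %g, %g) rad, delays = (%g, %g, %g) + %g samples, noise sigma = %g\n",
              x$phase_coeffs[1], x$phase_coeffs[2], x$phase_coeffs[3],
              x$delays[1], x$delays[2], x$delays[3], x$global_delay,
              x$noise_sigma))
  invisible(x)
}

#' Apply the imperfection forward model to spoke geometry
#'
#' For a spoke with unit direction d and readout sample spacing
#' `dk` (cycles/voxel between consecutive samples), the effective k-space
#' position of every sample is the nominal one minus a rigid shift
#' `dk_shift = s_par * d + v_perp`, with the along-readout component
#' `s_par = sum_a (tau_a + global) d_a^2 * dk` and the perpendicular
#' component `v_perp_a = (tau_a d_a - (sum_b tau_b d_b^2) d_a) * dk`.
#' Isotropic delays therefore produce a pure along-readout shift. In
#' addition each spoke acquires the constant direction-odd phase
#' `c . d` (radians).
#'
#' @param spokes A `spoke_set` (rows define directions).
#' @param model An [imperfection_model()].
#' @param cfg Trajectory configuration (for sample spacing); defaults to
#'   the one attached to `spokes`.
#' @return List with `shift` (N x 3 matrix of k-space shifts, cycles/voxel)
#'   and `phase` (length-N vector of additive spoke phases, radians).
#' @export
corrupt_spokes <- function(spokes, model, cfg = attr(spokes, "cfg")) {
  d <- spoke_directions(spokes)
  dk <- 2 * cfg$k_max / (cfg$samples_per_spoke - 1)
  tau <- model$delays
  d2 <- d^2
  proj <- as.vector(d2 %*% tau)            # sum_a tau_a d_a^2
  s_par <- (proj + model$global_delay) * dk
  v_perp <- (sweep(d, 2, tau, `*`) - proj * d) * dk
  shift <- s_par * d + v_perp
  phase <- as.vector(d %*% model$phase_coeffs)
  list(shift = shift, phase = phase)
}

#' K-space data container
#'
#' Holds complex samples per spoke x readout sample x coil together with
#' the nominal sample coordinates (what the reconstruction believes was
#' acquired) and the effective coordinates (where the corrupted system
#' actually sampled).
#'
#' @param samples Complex array `[spokes, M, coils]`.
#' @param nominal_coords Array `[spokes, M, 3]` (cycles/voxel).
#' @param effective_coords Same shape as `nominal_coords`.
#' @param spokes The `spoke_set` the data belong to.
#' @param cfg Trajectory configuration.
#' @param meta Optional named list of provenance entries.
#' @return Object of class `kspace_data`.
#' @export
kspace_data <- function(samples, nominal_coords, effective_coords, spokes,
                        cfg = attr(spokes, "cfg"), meta = list()) {
  if (length(dim(samples)) == 2L)
    samples <- array(samples, dim = c(dim(samples), 1L))
  stopifnot(length(dim(samples)) == 3L,
            all(dim(samples)[1:2] == dim(nominal_coords)[1:2]),
            dim(nominal_coords)[3] == 3L,
            all(dim(effective_coords) == dim(nominal_coords)),
            dim(samples)[1] == nrow(spokes))
  structure(list(samples = samples,
                 nominal_coords = nominal_coords,
                 effective_coords = effective_coords,
                 spokes = spokes,
                 cfg = cfg,
                 center_index = center_sample_index(dim(samples)[2]),
                 meta = meta),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<kspace_data> %d spokes x %d samples x %d coil(s)%s\n",
              d[1], d[2], d[3],
              if (isTRUE(x$meta$corrected)) " (corrected)" else ""))
  invisible(x)
}

#' @export
#' @rdname kspace_data
n_coils <- function(x) dim(x$samples)[3]

complex_noise <- function(n, sigma) {
  sigma / sqrt(2) * complex(real = rnorm(n), imaginary = rnorm(n))
}

#' Simulate a radial acquisition of an analytic phantom
#'
#' Evaluates the phantom's analytic Fourier transform at the *effective*
#' (corrupted) sample coordinates, multiplies each spoke by its
#' direction-odd constant phase, and adds seeded complex Gaussian noise.
#' The returned data keep the *nominal* coordinates for reconstruction:
#' the mismatch between the two is the mechanism by which the artifacts
#' under study arise. With coil profiles, the sensitivity-weighted
#' rasterized phantom is forward-transformed (type-2 gridding NUFFT) at
#' the same effective coordinates per coil.
#'
#' @param phantom A [phantom_spec()].
#' @param spokes A `spoke_set`.
#' @param model An [imperfection_model()] (default: identity).
#' @param coil_profiles Optional complex array `[m, m, m, coils]` of coil
#'   sensitivities (see [gaussian_coil_profiles()]); `NULL` for the
#'   single-coil analytic path.
#' @param seed Integer seed for the noise stream.
#' @param amplitudes Optional per-compartment amplitude overrides (e.g.
#'   from [bssfp_contrast_weights()]).
#' @param cfg Trajectory configuration; defaults to the one attached to
#'   `spokes`.
#' @return A [kspace_data()] object.
#' @export
simulate_acquisition <- function(phantom, spokes, model = imperfection_model(),
                                 coil_profiles = NULL, seed = 1L,
                                 amplitudes = NULL,
                                 cfg = attr(spokes, "cfg")) {
  nominal <- sample_positions(spokes, cfg)
  corr <- corrupt_spokes(spokes, model, cfg)
  effective <- nominal
  for (a in 1:3) effective[, , a] <- effective[, , a] - corr$shift[, a]
  ns <- nrow(spokes); M <- cfg$samples_per_spoke
  kflat <- matrix(effective, ncol = 3L)    # (spoke, sample) in column-major
  if (is.null(coil_profiles)) {
    vals <- phantom_kspace(phantom, kflat, amplitudes)
    samples <- array(vals, dim = c(ns, M, 1L))
  } else {
    msz <- dim(coil_profiles)[1]
    nc <- dim(coil_profiles)[4]
    vol <- rasterize_phantom(phantom, msz, amplitudes)
    samples <- array(0 + 0i, dim = c(ns, M, nc))
    for (cix in seq_len(nc)) {
      vals <- nufft_forward(vol * coil_profiles[, , , cix], kflat)
      samples[, , cix] <- vals
    }
  }
  samples <- samples * array(exp(1i * corr$phase), dim = dim(samples))
  if (model$noise_sigma > 0) {
    center_mag <- Mod(phantom_kspace(phantom, c(0, 0, 0), amplitudes))
    set.seed(as.integer(seed))
    samples <- samples + array(complex_noise(length(samples),
                                             model$noise_sigma * center_mag),
                               dim = dim(samples))
  }
  kspace_data(samples, nominal, effective, spokes, cfg,
              meta = list(model = model, seed = seed,
                          n_compartments = length(phantom$compartments)))
}

#' Balanced-SSFP contrast weights for a tissue phantom
#'
#' Replaces each compartment's amplitude with the complex steady-state
#' balanced-SSFP signal of its tissue at the given RF phase increment
#' (see [bssfp_profile()]), enabling simulation of a phase-cycled series.
#'
#' @param phantom A [phantom_spec()] whose compartments carry tissue.
#' @param seq_params A [sequence_params()].
#' @param phase_increment RF phase increment in degrees.
#' @return Complex vector of per-compartment amplitudes.
#' @export
bssfp_contrast_weights <- function(phantom, seq_params, phase_increment) {
  vapply(phantom$compartments, function(cc) {
    if (is.null(cc$tissue))
      stop("bssfp_contrast_weights requires tissue parameters in every compartment")
    sp <- seq_params
    sp$rf_phase_increments <- phase_increment
    bssfp_profile(cc$tissue, sp)$signal[1]
  }, complex(1))
}

#' Simulate and reconstruct a phase-cycled bSSFP series
#'
#' Runs one acquisition + reconstruction per RF phase increment, with the
#' compartment amplitudes set by the steady-state signal of each tissue at
#' that increment. The zeroth-order phase coefficients of the imperfection
#' model can drift across the series via per-increment multipliers,
#' emulating the slow change of the eddy-current state over a long
#' phase-cycled scan; a drift of the order of +-20 percent is what makes
#' trajectory phase errors catastrophic for mapping, because an
#' increment-independent corruption only rescales the whole profile by a
#' constant complex factor, which the ellipse inversion absorbs.
#'
#' @param phantom A [phantom_spec()] with tissue compartments.
#' @param spokes A `spoke_set`.
#' @param seq_params A [sequence_params()].
#' @param model Base [imperfection_model()].
#' @param recon_cfg A [recon_config()]; if `NULL` the raw [kspace_data()]
#'   objects are returned instead of reconstructions.
#' @param phase_drift Numeric vector of per-increment multipliers applied
#'   to `model$phase_coeffs` (recycled), or `NULL` for a stable scanner.
#' @param seed Base seed; increment j uses `seed + j`.
#' @return List of complex volumes (or `kspace_data` objects), one per RF
#'   phase increment.
#' @export
phase_cycled_series <- function(phantom, spokes, seq_params,
                                model = imperfection_model(),
                                recon_cfg = NULL, phase_drift = NULL,
                                seed = 1L) {
  incs <- seq_params$rf_phase_increments
  if (!is.null(phase_drift))
    phase_drift <- rep_len(phase_drift, length(incs))
  lapply(seq_along(incs), function(j) {
    mj <- model
    if (!is.null(phase_drift))
      mj$phase_coeffs <- mj$phase_coeffs * phase_drift[j]
    amps <- bssfp_contrast_weights(phantom, seq_params, incs[j])
    kd <- simulate_acquisition(phantom, spokes, mj, amplitudes = amps,
                               seed = seed + j)
    if (is.null(recon_cfg)) kd else recon_radial(kd, recon_cfg)$image
  })
}
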