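#' Reconstruction configuration
#'
#' @param matrix_size Output image edge length (>= 8 voxels).
#' @param oversampling Grid oversampling factor in `[1, 2]`.
#' @param kernel_width Gridding kernel support in grid cells.
#' @param exclude_si Drop the first (navigator) spoke of each interleave
#'   before reconstruction.
#' @param calib_region Edge length of the central k-space calibration
#'   block (in regridded k-space samples) used for coil sensitivity
#'   estimation.
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(matrix_size, oversampling = 1.5, kernel_width = 5,
                         exclude_si = TRUE, calib_region = 4) {
  stopifnot(matrix_size >= 8, oversampling >= 1, oversampling <= 2)
  if (calib_region > matrix_size)
    stop("calib_region larger than matrix")
  structure(list(matrix_size = as.integer(matrix_size),
                 oversampling = oversampling,
                 kernel_width = kernel_width,
                 exclude_si = exclude_si,
                 calib_region = as.integer(calib_region)),
            class = "recon_config")
}

# Kaiser-Bessel shape parameter (Beatty's minimal-aliasing choice).
kb_beta <- function(width, os) {
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

# Grid size for a recon config (even, >= matrix_size).
grid_size <- function(cfg) {
  G <- ceiling(cfg$matrix_size * cfg$oversampling / 2) * 2
  as.integer(G)
}

# Fourier transform of the gridding kernel at frequencies xi
# (cycles per grid cell), by Simpson quadrature over the kernel support.
kb_transform <- function(xi, width, beta, n_quad = 257L) {
  u <- seq(0, width / 2, length.out = n_quad)
  ku <- as.numeric(kb_kernel_eval(u, width, beta))
  h <- u[2] - u[1]
  w <- rep(c(4, 2), length.out = n_quad - 2L)
  w <- c(1, w, 1) * h / 3
  # C(xi) = 2 * int_0^{W/2} kb(u) cos(2 pi u xi) du
  vapply(xi, function(x) 2 * sum(w * ku * cos(2 * pi * u * x)), numeric(1))
}

fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Radial density-compensation weights
#'
#' For 3D radial sampling the sample density falls off as `1 / |k|^2`, so
#' each sample is weighted by `|k|^2`; the k-space-center sample gets the
#' analytic shell-limit weight `(dk/2)^2 / 3` (with `dk` the readout
#' sample spacing). Weights are normalized to sum to 1 over the dataset.
#'
#' @param kdata A [kspace_data()] object (nominal coordinates are used).
#' @return Numeric matrix `[spokes, samples]` of nonnegative weights.
#' @export
density_weights <- function(kdata) {
  co <- kdata$nominal_coords
  ns <- dim(co)[1]; M <- dim(co)[2]
  # radial-geometry check: every sample must be collinear with its spoke
  d <- spoke_directions(kdata$spokes)
  cross_mag <- abs(co[, , 1] * d[, 2] - co[, , 2] * d[, 1]) +
    abs(co[, , 2] * d[, 3] - co[, , 3] * d[, 2]) +
    abs(co[, , 3] * d[, 1] - co[, , 1] * d[, 3])
  if (any(cross_mag > 1e-8))
    stop("unsupported geometry: samples are not on lines through the origin")
  r2 <- co[, , 1]^2 + co[, , 2]^2 + co[, , 3]^2
  dk <- 2 * kdata$cfg$k_max / (M - 1)
  w <- r2
  w[r2 < (dk / 4)^2] <- (dk / 2)^2 / 3
  w / sum(w)
}

#' Adjoint gridding reconstruction of one coil
#'
#' Convolves the density-weighted samples onto an oversampled Cartesian
#' grid with a Kaiser-Bessel kernel, inverse Fourier transforms, crops to
#' the nominal matrix and divides out the kernel's apodization, so that
#' the result approximates the exact adjoint non-uniform DFT
#' `img(x) = sum_j w_j s_j exp(+2i pi k_j . x)` at voxel offsets x.
#'
#' @param kdata A [kspace_data()] object.
#' @param weights Per-sample weights from [density_weights()].
#' @param cfg A [recon_config()].
#' @return Complex array `[m, m, m, coils]` of per-coil images.
#' @export
adjoint_grid <- function(kdata, weights, cfg) {
  m <- cfg$matrix_size
  G <- grid_size(cfg)
  W <- cfg$kernel_width
  beta <- kb_beta(W, G / m)
  co <- kdata$nominal_coords
  if (max(abs(co)) > kdata$cfg$k_max + 1e-9)
    stop("sample coordinate out of range +-k_max")
  coords <- matrix(co, ncol = 3L) * G  # grid units
  nc <- n_coils(kdata)
  ax <- seq_len(m) - m / 2 - 1
  deapo1 <- kb_transform(ax / G, W, beta)
  deapo <- outer(outer(deapo1, deapo1), deapo1)
  lo <- G / 2 - m / 2 + 1; hi <- G / 2 + m / 2
  out <- array(0 + 0i, dim = c(m, m, m, nc))
  for (cix in seq_len(nc)) {
    vals <- as.complex(kdata$samples[, , cix]) * as.vector(weights)
    grid <- grid_spread3(coords, vals, G, W, beta)
    img <- fftshift3(fft(fftshift3(grid), inverse = TRUE))
    out[, , , cix] <- img[lo:hi, lo:hi, lo:hi] / deapo
  }
  out
}

#' Forward gridding (type-2) non-uniform Fourier transform
#'
#' Evaluates `F(k_j) = sum_x img(x) exp(-2i pi k_j . x)` (x in voxel
#' offsets from the volume center) by apodization correction, oversampled
#' FFT and kernel interpolation. Used by the multi-coil acquisition
#' simulator.
#'
#' @param vol Complex cubic array (image, matrix m).
#' @param k Matrix of k-space positions (rows, cycles/voxel).
#' @param oversampling Grid oversampling factor.
#' @param kernel_width Kernel support in grid cells.
#' @return Complex vector, one value per row of `k`.
#' @export
nufft_forward <- function(vol, k, oversampling = 2, kernel_width = 6) {
  m <- dim(vol)[1]
  G <- as.integer(ceiling(m * oversampling / 2) * 2)
  W <- kernel_width
  beta <- kb_beta(W, G / m)
  ax <- seq_len(m) - m / 2 - 1
  deapo1 <- kb_transform(ax / G, W, beta)
  deapo <- outer(outer(deapo1, deapo1), deapo1)
  pad <- array(0 + 0i, dim = rep(G, 3))
  lo <- G / 2 - m / 2 + 1; hi <- G / 2 + m / 2
  pad[lo:hi, lo:hi, lo:hi] <- vol / deapo
  grid <- fftshift3(fft(fftshift3(pad)))
  grid_interp3(grid, k * G, G, W, beta)
}

#' Remove the navigator (SI) spokes from a dataset
#'
#' The first spoke of each interleave is acquired for self-gating and is
#' not used for image reconstruction. Removal is idempotent.
#'
#' @param kdata A [kspace_data()] object.
#' @return A [kspace_data()] with all `j = 1` spokes dropped; the number
#'   removed is recorded in `meta$si_removed`.
#' @export
exclude_si_spokes <- function(kdata) {
  keep <- !kdata$spokes$is_si_spoke
  if (all(keep)) {
    kdata$meta$si_removed <- 0L
    return(kdata)
  }
  subset_kspace(kdata, keep, meta = c(kdata$meta,
                                      list(si_removed = sum(!keep))))
}

# Row subsetting of a kspace_data object.
subset_kspace <- function(kdata, keep, meta = kdata$meta) {
  sp <- kdata$spokes[keep, , drop = FALSE]
  attr(sp, "cfg") <- kdata$cfg
  class(sp) <- c("spoke_set", "data.frame")
  kspace_data(kdata$samples[keep, , , drop = FALSE],
              kdata$nominal_coords[keep, , , drop = FALSE],
              kdata$effective_coords[keep, , , drop = FALSE],
              sp, kdata$cfg, meta)
}

#' Adaptive coil combination
#'
#' Coil sensitivities are estimated from low-resolution coil images
#' formed from a centered `calib_region`^3 block of the regridded
#' Cartesian k-space of each coil image; the combined image is the
#' sensitivity-weighted projection `sum_c conj(s_c) img_c` with
#' `s_c = L_c / sqrt(sum_c |L_c|^2)`. Single-coil input is returned
#' unchanged.
#'
#' @param per_coil Complex array `[m, m, m, coils]`.
#' @param cfg A [recon_config()].
#' @return Complex array `[m, m, m]`.
#' @export
coil_combine <- function(per_coil, cfg) {
  dims <- dim(per_coil)
  if (length(dims) == 3L || dims[4] == 1L) {
    if (length(dims) == 4L) dim(per_coil) <- dims[1:3]
    return(per_coil)
  }
  m <- dims[1]; nc <- dims[4]
  cr <- cfg$calib_region
  lo <- m / 2 - cr / 2 + 1; hi <- m / 2 + cr / 2
  lowres <- array(0 + 0i, dim = dims)
  for (cix in seq_len(nc)) {
    ksp <- fftshift3(fft(fftshift3(per_coil[, , , cix])))
    mask <- array(0, dim = rep(m, 3))
    mask[lo:hi, lo:hi, lo:hi] <- 1
    lowres[, , , cix] <- fftshift3(fft(fftshift3(ksp * mask), inverse = TRUE)) / m^3
  }
  norm <- sqrt(apply(Mod(lowres)^2, 1:3, sum))
  norm[norm == 0] <- 1
  combined <- array(0 + 0i, dim = dims[1:3])
  for (cix in seq_len(nc)) {
    s <- lowres[, , , cix] / norm
    combined <- combined + Conj(s) * per_coil[, , , cix]
  }
  combined
}

#' Full radial reconstruction pipeline
#'
#' Optionally removes the SI spokes, computes density weights, grids each
#' coil and combines coils.
#'
#' @param kdata A [kspace_data()] object.
#' @param cfg A [recon_config()].
#' @return Object of class `recon_result` with elements `image` (complex
#'   volume), `per_coil` (complex `[m,m,m,coils]`), `cfg`, and
#'   `provenance` (trajectory design, SI exclusion, correction flags).
#' @export
recon_radial <- function(kdata, cfg) {
  if (cfg$exclude_si) kdata <- exclude_si_spokes(kdata)
  w <- density_weights(kdata)
  per_coil <- adjoint_grid(kdata, w, cfg)
  img <- coil_combine(per_coil, cfg)
  structure(list(image = img, per_coil = per_coil, cfg = cfg,
                 provenance = list(design = kdata$cfg$design,
                                   n_spokes_used = nrow(kdata$spokes),
                                   si_removed = kdata$meta$si_removed,
                                   corrected = isTRUE(kdata$meta$corrected))),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> matrix %d, %s design, %d spokes used%s\n",
              x$cfg$matrix_size, x$provenance$design,
              x$provenance$n_spokes_used,
              if (isTRUE(x$provenance$corrected)) " (corrected data)" else ""))
  invisible(x)
}

#' Magnitude and phase views of a reconstruction
#'
#' @param x A `recon_result` or complex array.
#' @return Numeric array; phase lies in `(-pi, pi]`.
#' @export
magnitude_view <- function(x) {
  if (inherits(x, "recon_result")) x <- x$image
  Mod(x)
}

#' @rdname magnitude_view
#' @export
phase_view <- function(x) {
  if (inherits(x, "recon_result")) x <- x$image
  ph <- Arg(x)
  ph[ph <= -pi] <- pi   # signed zeros can yield -pi; report (-pi, pi]
  ph
}

#' Magnitude and phase difference maps between two reconstructions
#'
#' Magnitude difference is `|a| - |b|`; phase difference is the wrapped
#' angle of `a * conj(b)`.
#'
#' @param a,b `recon_result` objects (or complex volumes) of equal size.
#' @return List with `magnitude` and `phase` arrays.
#' @export
difference_map <- function(a, b) {
  if (inherits(a, "recon_result")) a <- a$image
  if (inherits(b, "recon_result")) b <- b$image
  if (!all(dim(a) == dim(b))) stop("difference_map: shape mismatch")
  list(magnitude = Mod(a) - Mod(b),
       phase = Arg(a * Conj(b)))
}

#' Write a reconstruction to NIfTI files
#'
#' Magnitude and phase are written as separate NIfTI volumes and the
#' provenance as a JSON sidecar.
#'
#' @param res A `recon_result`.
#' @param prefix Output path prefix; files `<prefix>_mag.nii.gz`,
#'   `<prefix>_phase.nii.gz` and `<prefix>.json` are created.
#' @return `prefix`, invisibly.
#' @export
write_recon_nifti <- function(res, prefix) {
  RNifti::writeNifti(magnitude_view(res), paste0(prefix, "_mag.nii.gz"))
  RNifti::writeNifti(phase_view(res), paste0(prefix, "_phase.nii.gz"))
  jsonlite::write_json(res$provenance, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
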