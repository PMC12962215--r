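#' Multi-compartment spherical digital phantom
#'
#' A phantom is a list of spherical compartments, each with a center (in
#' voxel units of the target matrix, origin at the volume center), a
#' radius (voxels) and either a fixed complex amplitude or a tissue
#' parameter set (`T1`, `T2` in ms, `off_resonance` in Hz,
#' `proton_density` in arbitrary units) for balanced-SSFP contrast
#' simulation. Overlapping compartments add.
#'
#' @param compartments List of lists with fields `center` (length-3
#'   numeric), `radius` (> 0), and `amplitude` (complex scalar) and/or
#'   `tissue` (list with T1, T2, off_resonance, proton_density).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(compartments) {
  stopifnot(length(compartments) >= 1L)
  has_tissue <- vapply(compartments, function(cc) !is.null(cc$tissue), logical(1))
  if (any(has_tissue) && !all(has_tissue))
    stop("either all compartments carry tissue parameters or none")
  comps <- lapply(compartments, function(cc) {
    stopifnot(length(cc$center) == 3L, cc$radius > 0)
    if (is.null(cc$amplitude)) cc$amplitude <- 1 + 0i
    cc$amplitude <- as.complex(cc$amplitude)
    if (!is.null(cc$tissue)) {
      tt <- cc$tissue
      stopifnot(!is.null(tt$T1), !is.null(tt$T2))
      if (is.null(tt$off_resonance)) tt$off_resonance <- 0
      if (is.null(tt$proton_density)) tt$proton_density <- 1
      if (tt$T1 <= 0 || tt$T2 <= 0 || tt$T2 > tt$T1)
        stop("tissue must satisfy T1 >= T2 > 0")
      cc$tissue <- tt
    }
    cc
  })
  structure(list(compartments = comps), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d spherical compartment(s)%s\n",
              length(x$compartments),
              if (!is.null(x$compartments[[1]]$tissue)) " with tissue parameters" else ""))
  invisible(x)
}

#' A single centered water ball, the salt-water phantom stand-in
#'
#' @param radius Ball radius in voxels.
#' @param amplitude Complex amplitude.
#' @return A `phantom_spec` with one compartment.
#' @export
ball_phantom <- function(radius = 15, amplitude = 1 + 0i) {
  phantom_spec(list(list(center = c(0, 0, 0), radius = radius,
                         amplitude = amplitude)))
}

#' A miniature system-phantom layout: vials on a ring inside a water bath
#'
#' Emulates the geometry of a quantitative MRI system phantom: a large
#' background sphere plus `n_vials` small vials arranged on a ring in the
#' central plane, each with its own T1/T2.
#'
#' @param t1 Vial T1 values (ms), recycled to `n_vials`.
#' @param t2 Vial T2 values (ms), same length as `t1`.
#' @param n_vials Number of vials.
#' @param ring_radius Ring radius in voxels.
#' @param vial_radius Vial radius in voxels.
#' @param bath_radius Radius of the background sphere (0 disables it).
#' @param bath_tissue Tissue list for the bath.
#' @return A `phantom_spec`.
#' @export
system_phantom <- function(t1, t2, n_vials = length(t1), ring_radius = 13,
                           vial_radius = 4, bath_radius = 20,
                           bath_tissue = list(T1 = 3000, T2 = 1000,
                                              off_resonance = 0,
                                              proton_density = 0.3)) {
  stopifnot(length(t1) == length(t2), n_vials == length(t1))
  ang <- 2 * pi * (seq_len(n_vials) - 1) / n_vials
  centers <- lapply(seq_len(n_vials), function(i)
    c(ring_radius * cos(ang[i]), ring_radius * sin(ang[i]), 0))
  comps <- lapply(seq_len(n_vials), function(i) {
    list(center = centers[[i]], radius = vial_radius,
         tissue = list(T1 = t1[i], T2 = t2[i], off_resonance = 0,
                       proton_density = 1))
  })
  if (bath_radius > 0) {
    # overlapping compartments add, so carve a hole in the bath under each
    # vial with a negative-proton-density copy of the bath tissue
    holes <- lapply(centers, function(ctr) {
      ht <- bath_tissue; ht$proton_density <- -ht$proton_density
      list(center = ctr, radius = vial_radius, tissue = ht)
    })
    comps <- c(comps, holes,
               list(list(center = c(0, 0, 0), radius = bath_radius,
                         tissue = bath_tissue)))
  }
  phantom_spec(comps)
}

#' Analytic 3D Fourier transform of a uniform ball
#'
#' For a compartment of radius R, amplitude A, centered at c, evaluated at
#' k-space position k (cycles/voxel):
#' `A * V * 3 * (sin u - u cos u) / u^3 * exp(-2i pi k . c)` with
#' `u = 2 pi |k| R` and `V = 4/3 pi R^3`; the `u -> 0` limit is `A * V`.
#'
#' @param compartment One compartment of a [phantom_spec()].
#' @param k Matrix of k-space positions (rows) or a length-3 vector.
#' @return Complex vector of transform values.
#' @export
analytic_ball_transform <- function(compartment, k) {
  if (is.null(dim(k))) k <- matrix(k, ncol = 3)
  R <- compartment$radius
  V <- 4 / 3 * pi * R^3
  kn <- sqrt(rowSums(k^2))
  u <- 2 * pi * kn * R
  shape <- rep(1, length(u))
  nz <- u > 1e-8
  shape[nz] <- 3 * (sin(u[nz]) - u[nz] * cos(u[nz])) / u[nz]^3
  ph <- exp(-2i * pi * as.vector(k %*% compartment$center))
  compartment$amplitude * V * shape * ph
}

#' Analytic phantom k-space: sum of compartment ball transforms
#'
#' @param phantom A `phantom_spec`.
#' @param k Matrix of k-space positions (rows).
#' @param amplitudes Optional per-compartment complex amplitudes
#'   overriding the stored ones (used for bSSFP contrast).
#' @return Complex vector.
#' @export
phantom_kspace <- function(phantom, k, amplitudes = NULL) {
  if (is.null(dim(k))) k <- matrix(k, ncol = 3)
  out <- complex(length.out = nrow(k))
  for (i in seq_along(phantom$compartments)) {
    comp <- phantom$compartments[[i]]
    if (!is.null(amplitudes)) comp$amplitude <- amplitudes[i]
    out <- out + analytic_ball_transform(comp, k)
  }
  out
}

#' Rasterize a phantom onto an image grid
#'
#' Voxel centers lie at integer offsets from the volume center
#' (index i - matrix/2 - 1 along each axis, matching the reconstruction's
#' image coordinates).
#'
#' @param phantom A `phantom_spec`.
#' @param matrix_size Grid edge length.
#' @param amplitudes Optional per-compartment amplitude overrides.
#' @return Complex array `[matrix_size^3]`.
#' @export
rasterize_phantom <- function(phantom, matrix_size, amplitudes = NULL) {
  ax <- seq_len(matrix_size) - matrix_size / 2 - 1
  vol <- array(0 + 0i, dim = rep(matrix_size, 3))
  X <- array(rep(ax, times = matrix_size^2), dim = rep(matrix_size, 3))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  for (i in seq_along(phantom$compartments)) {
    comp <- phantom$compartments[[i]]
    amp <- if (is.null(amplitudes)) comp$amplitude else amplitudes[i]
    r2 <- (X - comp$center[1])^2 + (Y - comp$center[2])^2 + (Z - comp$center[3])^2
    vol <- vol + amp * (r2 <= comp$radius^2)
  }
  vol
}

#' Binary support mask of a phantom
#'
#' @inheritParams rasterize_phantom
#' @param dilate Radius increase in voxels applied to every compartment
#'   (used to keep boundary ringing out of artifact metrics).
#' @return Logical array `[matrix_size^3]`.
#' @export
phantom_support <- function(phantom, matrix_size, dilate = 0) {
  ph <- phantom
  ph$compartments <- lapply(ph$compartments, function(cc) {
    cc$radius <- cc$radius + dilate; cc$amplitude <- 1 + 0i; cc$tissue <- NULL
    cc
  })
  Mod(rasterize_phantom(ph, matrix_size)) > 0
}

#' Smooth synthetic coil sensitivity profiles
#'
#' Gaussian-weighted complex fields for `n_coils` coils placed on a ring
#' around the volume; no attempt is made to model a real array geometry.
#'
#' @param n_coils Number of coils.
#' @param matrix_size Grid edge length.
#' @param width Gaussian width as a fraction of the matrix (default 0.7).
#' @return Complex array `[matrix_size, matrix_size, matrix_size, n_coils]`.
#' @export
gaussian_coil_profiles <- function(n_coils, matrix_size, width = 0.7) {
  ax <- seq_len(matrix_size) - matrix_size / 2 - 1
  X <- array(rep(ax, times = matrix_size^2), dim = rep(matrix_size, 3))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  out <- array(0 + 0i, dim = c(rep(matrix_size, 3), n_coils))
  sig <- width * matrix_size / 2
  R <- matrix_size / 2
  for (cix in seq_len(n_coils)) {
    a <- 2 * pi * (cix - 1) / n_coils
    cx <- R * cos(a); cy <- R * sin(a); cz <- 0.3 * R * sin(2 * a)
    r2 <- (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2
    mag <- exp(-r2 / (2 * sig^2))
    pha <- 0.5 * ((X - cx) + (Y - cy)) / matrix_size  # slowly varying phase
    out[, , , cix] <- mag * exp(2i * pi * pha)
  }
  out
}
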