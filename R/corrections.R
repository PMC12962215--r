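#' Extract the k-space-center phase of every spoke
#'
#' The phase at the readout center sample, per spoke and coil. Entries
#' whose center-sample magnitude is (numerically) zero are flagged
#' `NA` rather than silently reported as zero phase.
#'
#' @param kdata A [kspace_data()] object.
#' @return Object of class `center_phase_table`: data frame with one row
#'   per spoke x coil, columns `n`, `j`, `k`, `coil`, `theta`, `phi`,
#'   `dx`, `dy`, `dz`, `phase` (radians in `(-pi, pi]`, `NA` if
#'   undefined) and `magnitude`.
#' @export
extract_center_phase <- function(kdata) {
  ci <- kdata$center_index
  nc <- n_coils(kdata)
  sp <- kdata$spokes
  rows <- lapply(seq_len(nc), function(cix) {
    s <- kdata$samples[, ci, cix]
    data.frame(n = sp$n, j = sp$j, k = sp$k, coil = cix,
               theta = sp$theta, phi = sp$phi,
               dx = sp$dx, dy = sp$dy, dz = sp$dz,
               phase = ifelse(Mod(s) < 1e-300, NA_real_, Arg(s)),
               magnitude = Mod(s))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("center_phase_table", "data.frame")
  out
}

#' Split a dataset by start hemisphere
#'
#' Partitions the spokes by the sign of their start direction's
#' z-component (ties to "upper"), so each half can be reconstructed as a
#' standalone dataset. Only meaningful for designs that populate both
#' hemispheres.
#'
#' @param kdata A [kspace_data()] object (or a `spoke_set`).
#' @return List with elements `upper` and `lower` of the same class as
#'   the input.
#' @export
split_hemispheres <- function(kdata) {
  sp <- if (inherits(kdata, "kspace_data")) kdata$spokes else kdata
  if (all(sp$hemisphere == "upper"))
    stop("single-hemisphere design: nothing to split")
  up <- sp$hemisphere == "upper"
  if (inherits(kdata, "kspace_data")) {
    list(upper = subset_kspace(kdata, up),
         lower = subset_kspace(kdata, !up))
  } else {
    cfg <- attr(sp, "cfg")
    mk <- function(rows) {
      out <- sp[rows, , drop = FALSE]
      attr(out, "cfg") <- cfg
      class(out) <- c("spoke_set", "data.frame")
      out
    }
    list(upper = mk(up), lower = mk(!up))
  }
}

#' Find the spatially closest opposing spoke for every spoke
#'
#' For each spoke with start direction d, the partner is the spoke in the
#' *opposite* start hemisphere whose start direction is closest to -d
#' (smallest angle between d_i and -d_j). Exhaustive search over all
#' candidate pairs; ties are broken by the lower acquisition index.
#'
#' @param spokes A `spoke_set` (or a [kspace_data()]).
#' @return Object of class `opposing_pair_map`: data frame with columns
#'   `n` (spoke), `partner` (its opposing spoke's acquisition index),
#'   `gap` (angle between d and -d_partner, radians in `[0, pi]`) and
#'   `hemisphere`.
#' @export
find_opposing <- function(spokes) {
  if (inherits(spokes, "kspace_data")) spokes <- spokes$spokes
  d <- spoke_directions(spokes)
  up <- spokes$hemisphere == "upper"
  if (!any(up) || all(up))
    stop("empty opposite hemisphere: opposing-spoke search needs both")
  partner <- integer(nrow(spokes))
  gap <- numeric(nrow(spokes))
  for (side in c(TRUE, FALSE)) {
    idx <- which(up == side)
    opp <- which(up != side)
    # angle(d_i, -d_j) minimal <=> dot(d_i, d_j) minimal
    dots <- d[idx, , drop = FALSE] %*% t(d[opp, , drop = FALSE])
    # ties: prefer lower acquisition index n among the opposite set
    ord <- order(spokes$n[opp])
    dots_o <- dots[, ord, drop = FALSE]
    best <- max.col(-dots_o, ties.method = "first")
    partner[idx] <- spokes$n[opp][ord][best]
    gap[idx] <- acos(pmin(1, pmax(-1, -dots_o[cbind(seq_along(idx), best)])))
  }
  out <- data.frame(n = spokes$n, partner = partner, gap = gap,
                    hemisphere = spokes$hemisphere)
  class(out) <- c("opposing_pair_map", "data.frame")
  out
}

#' Opposing-spoke constant-phase correction
#'
#' Multiplies every sample of spoke i (per coil independently) by a unit
#' constant built from the k-space-center phase of its opposing partner.
#' Under a direction-odd phase error the partner's center phase is the
#' negative of the spoke's own error, so the default `"cancel"`
#' convention (`S' = S * exp(+i * phi_opposing)`) removes the
#' spoke-dependent phase and leaves only a global constant;
#' `"literal"` applies `S' = S * exp(-i * phi_opposing)` instead, which
#' renders opposing pairs antisymmetric rather than consistent. Spokes
#' whose partner phase is undefined are left uncorrected and reported in
#' `meta$uncorrected_spokes`.
#'
#' @param kdata A [kspace_data()] object.
#' @param pairs An [find_opposing()] map for a dataset containing the
#'   partners (default: computed from `kdata`).
#' @param phases A [extract_center_phase()] table to look partner phases
#'   up in (default: extracted from `kdata`). Passing the table of the
#'   *full* dataset allows correcting a hemisphere subset.
#' @param convention `"cancel"` (default) or `"literal"` (see above).
#' @return A corrected [kspace_data()] object; per-spoke sample
#'   magnitudes are unchanged exactly.
#' @export
opposing_phase_correction <- function(kdata, pairs = NULL, phases = NULL,
                                      convention = c("cancel", "literal")) {
  convention <- match.arg(convention)
  if (is.null(pairs)) pairs <- find_opposing(kdata)
  if (is.null(phases)) phases <- extract_center_phase(kdata)
  sgn <- if (convention == "cancel") 1 else -1
  nc <- n_coils(kdata)
  uncorrected <- integer(0)
  for (cix in seq_len(nc)) {
    ph <- phases$phase[phases$coil == cix]
    names(ph) <- phases$n[phases$coil == cix]
    pp <- ph[as.character(pairs$partner[match(kdata$spokes$n, pairs$n)])]
    bad <- is.na(pp)
    if (any(bad)) {
      uncorrected <- union(uncorrected, kdata$spokes$n[bad])
      pp[bad] <- 0
    }
    kdata$samples[, , cix] <- kdata$samples[, , cix] *
      exp(1i * sgn * as.vector(pp))
  }
  kdata$meta$corrected <- TRUE
  kdata$meta$correction <- paste0("opposing-phase (", convention, ")")
  if (length(uncorrected)) {
    kdata$meta$uncorrected_spokes <- uncorrected
    warning(sprintf("%d spoke(s) left uncorrected (undefined partner phase)",
                    length(uncorrected)))
  }
  kdata
}

# Projection-space transform helpers: full spokes sample the readout line
# uniformly, so the spoke <-> projection mapping is an invertible complex
# matrix E[l, m] = exp(+2i pi kappa_m x_l) with x_l voxel offsets.
projection_operators <- function(kdata, n_proj = dim(kdata$samples)[2]) {
  M <- dim(kdata$samples)[2]
  kmax <- kdata$cfg$k_max
  kappa <- kmax * (1 - 2 * (seq_len(M) - 1) / (M - 1))
  # grid spacing (M-1)/M voxels: makes the M readout samples and M spatial
  # points a complete (invertible) Fourier pair; at integer spacing the two
  # edge samples (+-k_max, exactly one cycle apart) would alias.
  x <- (seq_len(n_proj) - (n_proj + 1) / 2) * (M - 1) / M
  E <- exp(2i * pi * outer(x, kappa))
  list(E = E, Einv = solve(E), x = x, kappa = kappa)
}

#' Opposing-projection gradient-delay estimation and correction
#'
#' Reproduces the self-correction of gradient delays enabled by opposing
#' spokes: (1) each spoke is transformed to projection (image) space
#' along the readout; (2) its partner's projection is evaluated on the
#' same spatial axis (the partner traverses the line in the opposite
#' direction); (3) the phase difference is combined across coils by a
#' magnitude-weighted complex sum (`coil_combine = "complex"`) or a plain
#' sum of angles (`"plain"`); (4) the unwrapped difference is fitted
#' linearly against readout position, restricted to positions where the
#' projection magnitude exceeds `mag_threshold` of its maximum; (5) half
#' the fitted slope and intercept (`mode = "half"`; both members of a
#' pair then move symmetrically) or the full difference (`mode = "full"`)
#' is removed as a linear phase in projection space before transforming
#' back.
#'
#' @param kdata A [kspace_data()] object (both hemispheres populated;
#'   at least 16 readout samples).
#' @param pairs An [find_opposing()] map (default computed from `kdata`).
#' @param mag_threshold Fit-region magnitude threshold, fraction of the
#'   per-projection maximum.
#' @param mode `"half"` or `"full"` difference application.
#' @param coil_combine `"complex"` or `"plain"` phase-difference
#'   combination across coils.
#' @return List with `kdata` (corrected) and `fits`: per-spoke data frame
#'   of slope `a` (rad per voxel), intercept `b` (rad), the implied
#'   readout shift in sample units (`delay_samples`), partner index and
#'   angular gap. Spokes with an empty fit region are left uncorrected
#'   (with a warning).
#' @export
gradient_delay_correction <- function(kdata, pairs = NULL,
                                      mag_threshold = 0.1,
                                      mode = c("half", "full"),
                                      coil_combine = c("complex", "plain")) {
  mode <- match.arg(mode)
  coil_combine <- match.arg(coil_combine)
  M <- dim(kdata$samples)[2]
  if (M < 16) stop("gradient-delay fit needs at least 16 readout samples")
  if (is.null(pairs)) pairs <- find_opposing(kdata)
  op <- projection_operators(kdata)
  nc <- n_coils(kdata)
  ns <- nrow(kdata$spokes)
  # projections of all spokes, all coils: [position, spoke, coil]
  proj <- array(0 + 0i, dim = c(M, ns, nc))
  for (cix in seq_len(nc))
    proj[, , cix] <- op$E %*% t(kdata$samples[, , cix])
  # The partner traverses the same line in the opposite direction: on the
  # common spatial axis (+d of the current spoke) its projection is the
  # spatial mirror. With the symmetric x grid used here (x_l = -x_{M+1-l}
  # up to the edge sample), mirroring is index reversal.
  row_of <- match(pairs$partner[match(kdata$spokes$n, pairs$n)], kdata$spokes$n)
  if (any(is.na(row_of)))
    stop("pair map refers to spokes not present in the dataset")
  a_fit <- b_fit <- rep(NA_real_, ns)
  skipped <- integer(0)
  new_samples <- kdata$samples
  full_i <- if (mode == "half") 0.5 else 1
  for (i in seq_len(ns)) {
    p_self <- proj[, i, , drop = FALSE]; dim(p_self) <- c(M, nc)
    p_opp <- proj[rev(seq_len(M)), row_of[i], , drop = FALSE]
    dim(p_opp) <- c(M, nc)
    if (coil_combine == "complex") {
      z <- rowSums(p_self * Conj(p_opp))
      dphi_wrapped <- Arg(z)
      wts <- Mod(z)
    } else {
      dphi_wrapped <- rowSums(Arg(p_self) - Arg(p_opp))
      dphi_wrapped <- atan2(sin(dphi_wrapped), cos(dphi_wrapped))
      wts <- rowSums(Mod(p_self) * Mod(p_opp))
    }
    mag <- sqrt(rowSums(Mod(p_self)^2))
    mask <- mag > mag_threshold * max(mag)
    if (!any(mask)) { skipped <- c(skipped, kdata$spokes$n[i]); next }
    idx <- which(mask)
    # 1D unwrap along the masked region
    dphi <- dphi_wrapped[idx]
    steps <- diff(dphi)
    steps <- atan2(sin(steps), cos(steps))
    dphi <- dphi[1] + c(0, cumsum(steps))
    fit <- stats::lm.wfit(cbind(1, op$x[idx]), dphi, wts[idx])
    b_fit[i] <- fit$coefficients[1]
    a_fit[i] <- fit$coefficients[2]
    corr <- exp(-1i * full_i * (a_fit[i] * op$x + b_fit[i]))
    for (cix in seq_len(nc))
      new_samples[i, , cix] <- op$Einv %*% (proj[, i, cix] * corr)
  }
  if (length(skipped))
    warning(sprintf("%d spoke(s) left uncorrected (empty fit region)",
                    length(skipped)))
  kdata$samples <- new_samples
  kdata$meta$corrected <- TRUE
  kdata$meta$correction <- paste0("gradient-delay (", mode, ")")
  dk <- 2 * kdata$cfg$k_max / (M - 1)
  # pair-difference slope a corresponds to twice the per-spoke shift:
  # a shift of delta samples gives projection phase -2 pi (delta dk) x
  fits <- data.frame(n = kdata$spokes$n,
                     partner = pairs$partner[match(kdata$spokes$n, pairs$n)],
                     gap = pairs$gap[match(kdata$spokes$n, pairs$n)],
                     a = a_fit, b = b_fit,
                     delay_samples = a_fit / (4 * pi * dk))
  list(kdata = kdata, fits = fits)
}
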