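#' Center-phase series and spherical point cloud
#'
#' Re-expresses a center-phase table as sortable series against the polar
#' and azimuthal angles, plus the 3D representation used to visualize the
#' phase pattern on the sphere (each spoke's direction scaled by its
#' phase value).
#'
#' @param phases A [extract_center_phase()] table.
#' @return List with `vs_theta` and `vs_phi` (data frames sorted by the
#'   respective angle) and `cloud` (data frame with columns x, y, z =
#'   direction * phase, plus n, coil, phase).
#' @export
center_phase_map <- function(phases) {
  stopifnot(nrow(phases) > 0)
  vs_theta <- phases[order(phases$theta), c("n", "coil", "theta", "phase")]
  vs_phi <- phases[order(phases$phi), c("n", "coil", "phi", "phase")]
  cloud <- data.frame(n = phases$n, coil = phases$coil,
                      x = phases$dx * phases$phase,
                      y = phases$dy * phases$phase,
                      z = phases$dz * phases$phase,
                      phase = phases$phase)
  list(vs_theta = vs_theta, vs_phi = vs_phi, cloud = cloud)
}

#' Great-circle jump statistics of an acquisition ordering
#'
#' The great-circle distance between the start directions of consecutively
#' acquired spokes, split into within-interleave transitions and
#' interleave-boundary transitions (last spoke of interleave k to first
#' spoke of interleave k+1). Large boundary jumps are the eddy-current
#' liability the continuous design removes.
#'
#' @param spokes A `spoke_set` in acquisition order.
#' @return List with `distances` (length N-1), `boundary` (logical,
#'   which transitions cross interleaves), and a `summary` data frame of
#'   median/mean/max per transition type.
#' @export
jump_statistics <- function(spokes) {
  stopifnot(nrow(spokes) >= 2L)
  d <- spoke_directions(spokes)
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
  dist <- acos(pmin(1, pmax(-1, dots)))
  boundary <- diff(spokes$k) != 0
  types <- list(within = !boundary, boundary = boundary)
  summ <- do.call(rbind, lapply(names(types), function(nm) {
    x <- dist[types[[nm]]]
    data.frame(type = nm, count = length(x),
               median = if (length(x)) stats::median(x) else NA_real_,
               mean = if (length(x)) mean(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_)
  }))
  list(distances = dist, boundary = boundary, summary = summ)
}

#' Artifact-energy metrics of a reconstruction
#'
#' Quantifies the signal smearing outside the known phantom support:
#' `artifact_energy` is the image energy outside the (dilated) support
#' divided by the energy inside the support; `axis_energy_fraction` is
#' the fraction of that outside energy lying within a cylinder of given
#' radius around the chosen axis through the volume center (the
#' trajectory's pole axis, along which these trajectories smear);
#' `interior_phase_mean`/`sd` summarize the phase inside the support.
#' The support is dilated before the inside/outside split so boundary
#' Gibbs ringing does not count as artifact.
#'
#' @param recon A `recon_result` or complex volume.
#' @param phantom The [phantom_spec()] that generated the data.
#' @param axis `"z"`, `"y"` or `"x"`: the axis for the cylinder metric.
#' @param dilate Support dilation in voxels.
#' @param cyl_radius Cylinder radius in voxels.
#' @return Object of class `artifact_report` (a list).
#' @export
artifact_metric <- function(recon, phantom, axis = "z", dilate = 2,
                            cyl_radius = 3) {
  img <- if (inherits(recon, "recon_result")) recon$image else recon
  m <- dim(img)[1]
  support <- phantom_support(phantom, m)
  if (!any(support)) stop("empty phantom support")
  dil <- phantom_support(phantom, m, dilate = dilate)
  e <- Mod(img)^2
  inside <- sum(e[support])
  outside <- sum(e[!dil])
  ax <- seq_len(m) - m / 2 - 1
  A <- array(rep(ax, times = m^2), dim = rep(m, 3))
  X <- A; Y <- aperm(A, c(2, 1, 3)); Z <- aperm(A, c(3, 2, 1))
  r2 <- switch(axis, z = X^2 + Y^2, y = X^2 + Z^2, x = Y^2 + Z^2)
  cyl <- r2 <= cyl_radius^2
  out_cyl <- sum(e[!dil & cyl])
  ph <- Arg(img[support])
  structure(list(artifact_energy = outside / inside,
                 axis_energy_fraction = if (outside > 0) out_cyl / outside else 0,
                 interior_phase_mean = mean(ph),
                 interior_phase_sd = stats::sd(ph),
                 interior_magnitude_cv = stats::sd(Mod(img[support])) /
                   mean(Mod(img[support])),
                 axis = axis),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report> artifact energy %.4g (%.1f%% within %s-axis cylinder); interior phase %.3f +- %.3f rad\n",
              x$artifact_energy, 100 * x$axis_energy_fraction, x$axis,
              x$interior_phase_mean, x$interior_phase_sd))
  invisible(x)
}

#' Retrospective undersampling of a radial dataset
#'
#' Retains every `factor`-th spoke in acquisition order
#' (`scheme = "stride"`, which preserves the golden-angle azimuthal
#' spread) or the first `N / factor` spokes (`scheme = "prefix"`).
#'
#' @param kdata A [kspace_data()] object.
#' @param factor Acceleration factor >= 1.
#' @param scheme `"stride"` or `"prefix"`.
#' @return An undersampled [kspace_data()].
#' @export
undersample <- function(kdata, factor, scheme = c("stride", "prefix")) {
  scheme <- match.arg(scheme)
  ns <- nrow(kdata$spokes)
  if (factor < 1) stop("acceleration factor must be >= 1")
  if (factor > ns) stop("acceleration factor exceeds the number of spokes")
  if (factor == 1) return(kdata)
  keep <- if (scheme == "stride") {
    seq_len(ns) %in% seq(1L, ns, by = as.integer(factor))
  } else {
    seq_len(ns) <= floor(ns / factor)
  }
  subset_kspace(kdata, keep,
                meta = c(kdata$meta, list(undersampling = factor,
                                          scheme = scheme)))
}

#' Export a center-phase table as CSV
#'
#' @param phases A [extract_center_phase()] table.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_center_phase_csv <- function(phases, file) {
  write.csv(phases[, c("n", "k", "j", "theta", "phi", "coil", "phase")],
            file, row.names = FALSE)
  invisible(file)
}
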