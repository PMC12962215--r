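#' @useDynLib phyllotaxr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm optim coef lm sd var
#' @importFrom utils write.csv read.csv
NULL

#' Golden angle in radians
#'
#' The azimuthal increment \eqn{\pi(3 - \sqrt 5) \approx 2.39996} rad
#' (137.51 degrees) that yields near-uniform azimuthal coverage of the
#' sphere for any spoke count.
#'
#' @return Angle in radians.
#' @export
golden_angle <- function() pi * (3 - sqrt(5))

#' Trajectory configuration for a 3D radial spiral phyllotaxis acquisition
#'
#' Defines one of the three spiral phyllotaxis designs:
#' \describe{
#'   \item{`original`}{polar angle runs pole to equator; every spoke starts
#'     in the upper k-space hemisphere.}
#'   \item{`pole_to_pole`}{polar angle runs continuously from one pole to
#'     the other, so spokes start from both hemispheres.}
#'   \item{`continuous`}{polar angle spans the full circle \eqn{[0, 2\pi)},
#'     returning each interleave to its starting region and minimizing
#'     k-space jumps between interleaves.}
#' }
#'
#' @param n_spokes Total number of readout spokes N. Must equal
#'   `n_interleaves * spokes_per_interleave`.
#' @param n_interleaves Number of interleaves K.
#' @param spokes_per_interleave Spokes per interleave J.
#' @param design One of `"original"`, `"pole_to_pole"`, `"continuous"`.
#' @param golden_angle Azimuthal increment in radians, in (0, 2*pi).
#' @param samples_per_spoke Number M of readout samples per full spoke,
#'   >= 3. Odd M places a sample exactly at the k-space center.
#' @param k_max Spatial-frequency bound in cycles/voxel (0.5 = Nyquist of
#'   an isotropic matrix).
#' @param si_spoke_mode `"formula"` leaves the first spoke of each
#'   interleave where the angular schedule puts it (near the pole);
#'   `"replace_with_z"` overwrites its direction with the +z axis, the
#'   conventional superior-inferior navigator spoke.
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(n_spokes,
                              n_interleaves,
                              spokes_per_interleave = n_spokes / n_interleaves,
                              design = c("original", "pole_to_pole", "continuous"),
                              golden_angle = phyllotaxr::golden_angle(),
                              samples_per_spoke = 49L,
                              k_max = 0.5,
                              si_spoke_mode = c("formula", "replace_with_z")) {
  design <- match.arg(design)
  si_spoke_mode <- match.arg(si_spoke_mode)
  n_spokes <- as.integer(n_spokes)
  n_interleaves <- as.integer(n_interleaves)
  spokes_per_interleave <- as.integer(spokes_per_interleave)
  if (n_spokes <= 0L || n_interleaves <= 0L || spokes_per_interleave <= 0L)
    stop("spoke and interleave counts must be positive")
  if (n_spokes != n_interleaves * spokes_per_interleave)
    stop("n_spokes must equal n_interleaves * spokes_per_interleave")
  if (!(golden_angle > 0 && golden_angle < 2 * pi))
    stop("golden_angle must lie in (0, 2*pi)")
  if (samples_per_spoke < 3L)
    stop("samples_per_spoke must be >= 3")
  if (design == "pole_to_pole" && n_spokes %% 2L != 0L)
    stop("pole_to_pole design requires an even number of spokes")
  if (design == "continuous" && n_spokes %% 4L != 0L)
    stop("continuous design requires a spoke count divisible by 4")
  structure(
    list(n_spokes = n_spokes, n_interleaves = n_interleaves,
         spokes_per_interleave = spokes_per_interleave, design = design,
         golden_angle = golden_angle,
         samples_per_spoke = as.integer(samples_per_spoke),
         k_max = k_max, si_spoke_mode = si_spoke_mode),
    class = "trajectory_config")
}

#' @export
print.trajectory_config <- function(x, ...) {
  cat(sprintf("<trajectory_config> %s design: N = %d spokes (%d interleaves x %d), M = %d samples, k_max = %g\n",
              x$design, x$n_spokes, x$n_interleaves,
              x$spokes_per_interleave, x$samples_per_spoke, x$k_max))
  invisible(x)
}

check_spoke_index <- function(n, N) {
  if (any(n < 1L | n > N)) stop("spoke index out of range 1..N")
  invisible(TRUE)
}

#' Azimuthal angle of the n-th spoke
#'
#' phi_n = (n * golden_angle) mod 2*pi.
#'
#' @param n Spoke index (1-based), vectorized.
#' @param cfg A [trajectory_config()].
#' @return Angle(s) in `[0, 2*pi)`.
#' @export
azimuthal_angle <- function(n, cfg) {
  check_spoke_index(n, cfg$n_spokes)
  (n * cfg$golden_angle) %% (2 * pi)
}

#' Polar angle schedules
#'
#' The three equal-area polar-angle schedules as a function of the spoke
#' index n and total spoke count N. The square-root progression
#' `theta = (pi/2) * sqrt(n/N)` is what makes the golden-angle spiral
#' phyllotaxis cover the sphere near-uniformly (equal solid angle per
#' spoke near the pole). `polar_angle_original()` runs from the pole to
#' the equator (`theta_N = pi/2`); `polar_angle_pole_to_pole()` continues
#' through the equator to the opposite pole (N even), mirroring the
#' square-root law from both ends; `polar_angle_continuous()` spans the
#' full circle `[0, 2*pi)` in four mirrored segments (N divisible by 4,
#' boundary values pi/2, pi, 3*pi/2 at n = N/4, N/2, 3N/4), so the
#' trajectory returns to the +z pole at n = N.
#'
#' @param n Spoke index (1-based), vectorized.
#' @param N Total number of spokes.
#' @return Polar angle(s) in radians.
#' @export
polar_angle_original <- function(n, N) {
  check_spoke_index(n, N)
  (pi / 2) * sqrt(n / N)
}

#' @rdname polar_angle_original
#' @export
polar_angle_pole_to_pole <- function(n, N) {
  check_spoke_index(n, N)
  if (N %% 2L != 0L) stop("pole_to_pole schedule requires even N")
  ifelse(n < N / 2,
         (pi / 2) * sqrt(2 * n / N),
         pi - (pi / 2) * sqrt(2 * (N - n) / N))
}

#' @rdname polar_angle_original
#' @export
polar_angle_continuous <- function(n, N) {
  check_spoke_index(n, N)
  if (N %% 4L != 0L) stop("continuous schedule requires N divisible by 4")
  # pmax() guards keep the unused ifelse branches out of sqrt's domain
  ifelse(n < N / 4, (pi / 2) * sqrt(4 * n / N),
  ifelse(n < N / 2, pi - (pi / 2) * sqrt(pmax(0, 4 * (N / 2 - n) / N)),
  ifelse(n < 3 * N / 4, pi + (pi / 2) * sqrt(pmax(0, 4 * (n - N / 2) / N)),
         2 * pi - (pi / 2) * sqrt(4 * (N - n) / N))))
}

#' Acquisition index of the j-th spoke in the k-th interleave
#'
#' n(j, k) = k + (j - 1) * K: consecutive interleaves advance the spoke
#' index by one, so that (for Fibonacci K) spokes within an interleave
#' share similar azimuths and the interleave sweeps the polar range.
#'
#' @param j Within-interleave index, 1..J (vectorized).
#' @param k Interleave index, 1..K (vectorized).
#' @param cfg A [trajectory_config()].
#' @return Spoke index n in 1..N.
#' @export
interleave_order <- function(j, k, cfg) {
  if (any(j < 1L | j > cfg$spokes_per_interleave))
    stop("within-interleave index out of range 1..J")
  if (any(k < 1L | k > cfg$n_interleaves))
    stop("interleave index out of range 1..K")
  as.integer(k + (j - 1L) * cfg$n_interleaves)
}

#' Unit direction of a spoke start point
#'
#' Converts spherical angles to a Cartesian unit vector
#' (sin(theta)cos(phi), sin(theta)sin(phi), cos(theta)). Polar angles in
#' (pi, 2*pi), as produced by the continuous schedule, are evaluated
#' literally; trigonometry makes theta in (pi, 2*pi) equivalent to polar
#' 2*pi - theta with azimuth phi + pi, which realizes the pole crossing.
#'
#' @param theta Polar angle(s), radians.
#' @param phi Azimuthal angle(s), radians.
#' @return A matrix with one row per angle pair and columns x, y, z.
#' @export
spoke_direction <- function(theta, phi) {
  cbind(x = sin(theta) * cos(phi),
        y = sin(theta) * sin(phi),
        z = cos(theta))
}

#' Build the ordered spoke set for a trajectory configuration
#'
#' Generates all N spokes in acquisition order (interleave k = 1..K outer,
#' within-interleave j = 1..J inner), with azimuth n * golden_angle mod
#' 2*pi and the design's polar schedule. The first spoke of each interleave
#' (j = 1) is flagged as the SI (navigator) spoke; with
#' `si_spoke_mode = "replace_with_z"` its direction is overwritten by the
#' +z axis. A start direction with z-component exactly 0 is assigned to the
#' upper hemisphere.
#'
#' @param cfg A [trajectory_config()].
#' @return An object of class `spoke_set`: a data frame in acquisition
#'   order with columns `n`, `j`, `k`, `theta`, `phi`, `dx`, `dy`, `dz`,
#'   `hemisphere`, `is_si_spoke`, carrying `cfg` as an attribute.
#' @export
build_spoke_set <- function(cfg) {
  stopifnot(inherits(cfg, "trajectory_config"))
  K <- cfg$n_interleaves; J <- cfg$spokes_per_interleave; N <- cfg$n_spokes
  k <- rep(seq_len(K), each = J)
  j <- rep(seq_len(J), times = K)
  n <- interleave_order(j, k, cfg)
  phi <- azimuthal_angle(n, cfg)
  theta <- switch(cfg$design,
                  original = polar_angle_original(n, N),
                  pole_to_pole = polar_angle_pole_to_pole(n, N),
                  continuous = polar_angle_continuous(n, N))
  d <- spoke_direction(theta, phi)
  is_si <- j == 1L
  if (cfg$si_spoke_mode == "replace_with_z" && any(is_si)) {
    d[is_si, ] <- rep(c(0, 0, 1), each = sum(is_si))
    theta[is_si] <- 0
  }
  hemisphere <- ifelse(d[, "z"] >= 0, "upper", "lower")
  ss <- data.frame(n = n, j = j, k = k, theta = theta, phi = phi,
                   dx = d[, "x"], dy = d[, "y"], dz = d[, "z"],
                   hemisphere = hemisphere, is_si_spoke = is_si)
  attr(ss, "cfg") <- cfg
  class(ss) <- c("spoke_set", "data.frame")
  ss
}

#' @export
print.spoke_set <- function(x, n = 6L, ...) {
  cfg <- attr(x, "cfg")
  cat(sprintf("<spoke_set> %d spokes (%s design), %d upper / %d lower hemisphere starts\n",
              nrow(x), if (is.null(cfg)) "?" else cfg$design,
              sum(x$hemisphere == "upper"), sum(x$hemisphere == "lower")))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat(sprintf("# ... %d more spokes\n", nrow(x) - n))
  invisible(x)
}

#' Spoke directions as a matrix
#' @param spokes A `spoke_set`.
#' @return N x 3 matrix of unit start directions.
#' @export
spoke_directions <- function(spokes) {
  as.matrix(spokes[, c("dx", "dy", "dz")])
}

#' Readout sample positions along spokes
#'
#' A full spoke samples the line through the k-space origin from
#' `+k_max * d` (start point) to `-k_max * d` inclusive, with M equally
#' spaced samples; for odd M the center sample lies exactly at the origin.
#'
#' @param spokes A `spoke_set` (or a subset of its rows).
#' @param cfg The trajectory configuration; defaults to the one attached
#'   to `spokes`.
#' @return Array `[n_spokes, M, 3]` of k-space coordinates (cycles/voxel).
#' @export
sample_positions <- function(spokes, cfg = attr(spokes, "cfg")) {
  M <- cfg$samples_per_spoke
  d <- spoke_directions(spokes)
  radii <- cfg$k_max * (1 - 2 * (seq_len(M) - 1) / (M - 1))  # +k_max .. -k_max
  out <- array(0, dim = c(nrow(d), M, 3L))
  for (a in 1:3) out[, , a] <- outer(d[, a], radii)
  out
}

#' Index of the k-space-center readout sample
#'
#' For odd M this sample lies exactly at the origin; for even M it is the
#' sample nearest the origin.
#'
#' @param M Samples per spoke.
#' @return 1-based readout index.
#' @export
center_sample_index <- function(M) {
  M <- as.integer(M)
  if (M %% 2L == 1L) (M + 1L) %/% 2L else M %/% 2L + 1L
}

#' Export / import a spoke set as CSV
#'
#' One spoke per row with columns n, j, k, theta, phi, dx, dy, dz. A JSON
#' sidecar `<file>.json` records the configuration (design, golden angle,
#' k_max, counts) so the set can be rebuilt losslessly.
#'
#' @param spokes A `spoke_set`.
#' @param file Path of the CSV file to write.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(spokes, file) {
  cfg <- attr(spokes, "cfg")
  write.csv(spokes[, c("n", "j", "k", "theta", "phi", "dx", "dy", "dz")],
            file, row.names = FALSE)
  jsonlite::write_json(unclass(cfg), paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  cfg <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  cfg <- trajectory_config(cfg$n_spokes, cfg$n_interleaves,
                           cfg$spokes_per_interleave, cfg$design,
                           cfg$golden_angle, cfg$samples_per_spoke,
                           cfg$k_max, cfg$si_spoke_mode)
  tab <- read.csv(file)
  ss <- build_spoke_set(cfg)
  # CSV is authoritative for angles/directions (it may hold a modified set)
  stopifnot(nrow(tab) == nrow(ss))
  ss[, c("n", "j", "k", "theta", "phi", "dx", "dy", "dz")] <- tab
  ss$hemisphere <- ifelse(ss$dz >= 0, "upper", "lower")
  ss$is_si_spoke <- ss$j == 1L
  ss
}
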