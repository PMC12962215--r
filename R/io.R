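#' Read phantom and imperfection-model configurations from YAML/JSON
#'
#' Field names follow the constructors: a phantom file holds a
#' `compartments` list (center, radius, amplitude, optional tissue); an
#' imperfection file holds `phase_coeffs`, `delays`, `global_delay`,
#' `noise_sigma`.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [phantom_spec()] or [imperfection_model()].
#' @export
read_phantom_config <- function(file) {
  spec <- read_config(file)
  spec$compartments <- lapply(spec$compartments, function(cc) {
    cc$center <- as.numeric(unlist(cc$center))
    if (!is.null(cc$amplitude)) cc$amplitude <- parse_complex(cc$amplitude)
    cc
  })
  phantom_spec(spec$compartments)
}

#' @rdname read_phantom_config
#' @export
read_imperfection_config <- function(file) {
  spec <- read_config(file)
  imperfection_model(
    phase_coeffs = as.numeric(unlist(spec$phase_coeffs %||% c(0, 0, 0))),
    delays = as.numeric(unlist(spec$delays %||% c(0, 0, 0))),
    global_delay = spec$global_delay %||% 0,
    noise_sigma = spec$noise_sigma %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(file) {
  if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
  else jsonlite::read_json(file, simplifyVector = TRUE)
}

parse_complex <- function(x) {
  if (is.character(x)) as.complex(x) else as.complex(x)
}

#' Export / import k-space data as CSV
#'
#' Long-format CSV with one sample per row (spoke row index, readout
#' index, coil, real and imaginary part, nominal and effective
#' coordinates); a `<file>.json` sidecar stores the trajectory
#' configuration and metadata. Intended for interchange at small problem
#' sizes; the in-memory arrays are the working representation.
#'
#' @param kdata A [kspace_data()] object.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_kspace_csv <- function(kdata, file) {
  d <- dim(kdata$samples)
  idx <- expand.grid(spoke = seq_len(d[1]), sample = seq_len(d[2]),
                     coil = seq_len(d[3]))
  co <- kdata$nominal_coords
  ce <- kdata$effective_coords
  flat <- cbind(idx,
                n = kdata$spokes$n[idx$spoke],
                re = Re(as.vector(kdata$samples)),
                im = Im(as.vector(kdata$samples)),
                kx = as.vector(co[, , 1])[idx$spoke + (idx$sample - 1) * d[1]],
                ky = as.vector(co[, , 2])[idx$spoke + (idx$sample - 1) * d[1]],
                kz = as.vector(co[, , 3])[idx$spoke + (idx$sample - 1) * d[1]],
                kx_eff = as.vector(ce[, , 1])[idx$spoke + (idx$sample - 1) * d[1]],
                ky_eff = as.vector(ce[, , 2])[idx$spoke + (idx$sample - 1) * d[1]],
                kz_eff = as.vector(ce[, , 3])[idx$spoke + (idx$sample - 1) * d[1]])
  write.csv(flat, file, row.names = FALSE)
  meta <- list(cfg = unclass(kdata$cfg),
               spokes = kdata$spokes[, c("n", "j", "k", "theta", "phi",
                                         "dx", "dy", "dz")])
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(file)
}

#' @rdname write_kspace_csv
#' @export
read_kspace_csv <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  cfgl <- meta$cfg
  cfg <- trajectory_config(cfgl$n_spokes, cfgl$n_interleaves,
                           cfgl$spokes_per_interleave, cfgl$design,
                           cfgl$golden_angle, cfgl$samples_per_spoke,
                           cfgl$k_max, cfgl$si_spoke_mode)
  tab <- read.csv(file)
  ns <- max(tab$spoke); M <- max(tab$sample); nc <- max(tab$coil)
  ord <- order(tab$coil, tab$sample, tab$spoke)
  tab <- tab[ord, ]
  samples <- array(complex(real = tab$re, imaginary = tab$im),
                   dim = c(ns, M, nc))
  sub <- tab[tab$coil == 1, ]
  nominal <- array(c(sub$kx, sub$ky, sub$kz), dim = c(ns, M, 3))
  effective <- array(c(sub$kx_eff, sub$ky_eff, sub$kz_eff), dim = c(ns, M, 3))
  sp <- as.data.frame(meta$spokes)
  present <- sp$n %in% unique(tab$n)
  full <- build_spoke_set(cfg)
  ss <- full[match(sp$n[present], full$n), , drop = FALSE]
  ss[, c("n", "j", "k", "theta", "phi", "dx", "dy", "dz")] <- sp[present, ]
  ss$hemisphere <- ifelse(ss$dz >= 0, "upper", "lower")
  ss$is_si_spoke <- ss$j == 1L
  attr(ss, "cfg") <- cfg
  class(ss) <- c("spoke_set", "data.frame")
  kspace_data(samples, nominal, effective, ss, cfg)
}
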