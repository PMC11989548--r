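#' The shipped "paper-qualitative" run configuration
#'
#' Default configuration of the whole pipeline: a calibration chosen so the
#' qualitative clinical behaviors hold (profile ordering of peroxidation
#' peaks, treatment hysteresis, mineralization lag, toxic reversal of the
#' dose response near gamma ~ 0.71), not a fit to any measured series.
#' Every value is overridable through [load_config()].
#'
#' @return A nested named list (the full default `RunConfig`).
#' @export
default_config <- function() {
  list(
    model = "lipid",
    solver = list(order = 0.8, step = 0.01, t_end = 6,
                  corrector_iterations = 1L),
    lipid = list(beta = 0.2, theta = 0.7, band_energy = 4.98,
                 observable_scale = 1, hdl_sign = -1, ox0 = 8,
                 normalization = 100),
    plaque = list(k1 = 0.3, area = 1, ox_level = 1, deposit_mass = 1,
                  h0 = 0.1, artery_length = 5, band_energy = 2.79,
                  observable_scale = 1),
    sweep = list(gamma_min = 0.10, gamma_max = 0.95, gamma_step = 0.05,
                 transform = FALSE, gamma_c = 0.70, c_tox = 0.03),
    profile = "160:50",
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (file path or literal YAML text), overlays it
#' on the shipped defaults ([default_config()]), and validates it.  Unknown
#' keys are rejected by name rather than silently ignored; range errors
#' name the offending key.
#'
#' @param source Path to a YAML file, or a YAML string, or `NULL` for the
#'   pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @examples
#' cfg <- load_config("solver:\n  order: 0.6\n")
#' cfg$solver$order
#' @export
load_config <- function(source = NULL) {
  base <- default_config()
  user <- list()
  if (!is.null(source)) {
    user <- if (is.character(source) && length(source) == 1L &&
                file.exists(source)) {
      yaml::read_yaml(source)
    } else {
      yaml::yaml.load(paste(source, collapse = "\n"))
    }
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  }
  cfg <- .merge_config(base, user, path = "")
  .validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

.merge_config <- function(base, user, path) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(base[[key]])) {
      if (!is.list(user[[key]])) {
        stop("config key ", full, " must be a mapping", call. = FALSE)
      }
      base[[key]] <- .merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  num1 <- function(x, key, lo = -Inf, hi = Inf, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("config key ", key, " must be a single finite number",
           call. = FALSE)
    }
    if (x < lo || x > hi || (lo_open && x == lo)) {
      stop("config key ", key, " out of range [", lo, ", ", hi, "]: ", x,
           call. = FALSE)
    }
    invisible(x)
  }
  if (!cfg$model %in% c("lipid", "plaque")) {
    stop("config key model must be 'lipid' or 'plaque'", call. = FALSE)
  }
  num1(cfg$solver$order, "solver.order", 0, 2, lo_open = TRUE)
  num1(cfg$solver$step, "solver.step", 0, Inf, lo_open = TRUE)
  num1(cfg$solver$t_end, "solver.t_end", 0, Inf, lo_open = TRUE)
  num1(cfg$solver$corrector_iterations, "solver.corrector_iterations", 1)
  # Therapeutic runs read gamma as a statin dose in (0, 1]; orders above 1
  # are admissible only through the toxic 1/gamma reading.
  if (cfg$model == "lipid" && !isTRUE(cfg$sweep$transform) &&
      cfg$solver$order > 1) {
    stop("config key solver.order: therapeutic lipid runs require ",
         "order <= 1 (got ", cfg$solver$order, ")", call. = FALSE)
  }
  num1(cfg$lipid$theta, "lipid.theta", 0, 1)
  num1(cfg$lipid$band_energy, "lipid.band_energy", 0, Inf, lo_open = TRUE)
  num1(cfg$lipid$observable_scale, "lipid.observable_scale", 0, Inf,
       lo_open = TRUE)
  num1(cfg$lipid$ox0, "lipid.ox0", 0)
  num1(cfg$lipid$normalization, "lipid.normalization", 0, Inf, lo_open = TRUE)
  if (!cfg$lipid$hdl_sign %in% c(-1, 1)) {
    stop("config key lipid.hdl_sign must be +1 or -1", call. = FALSE)
  }
  num1(cfg$plaque$k1, "plaque.k1", 0, Inf, lo_open = TRUE)
  num1(cfg$plaque$area, "plaque.area", 0, Inf, lo_open = TRUE)
  num1(cfg$plaque$ox_level, "plaque.ox_level", 0)
  num1(cfg$plaque$deposit_mass, "plaque.deposit_mass", 0)
  num1(cfg$plaque$h0, "plaque.h0", 0, Inf, lo_open = TRUE)
  num1(cfg$plaque$artery_length, "plaque.artery_length", 0, Inf,
       lo_open = TRUE)
  num1(cfg$sweep$gamma_min, "sweep.gamma_min", 0, 1, lo_open = TRUE)
  num1(cfg$sweep$gamma_max, "sweep.gamma_max", 0, 1, lo_open = TRUE)
  num1(cfg$sweep$gamma_step, "sweep.gamma_step", 0, 1, lo_open = TRUE)
  num1(cfg$sweep$gamma_c, "sweep.gamma_c", 0, 1, lo_open = TRUE)
  num1(cfg$sweep$c_tox, "sweep.c_tox", 0)
  .parse_profile(cfg$profile)   # errors if malformed
  invisible(cfg)
}

.parse_profile <- function(spec) {
  if (inherits(spec, "patient_profile")) return(spec)
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    stop("config key profile must look like 'LDL:HDL' (e.g. '160:50')",
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals)) || any(vals <= 0)) {
    stop("config key profile must contain two positive numbers",
         call. = FALSE)
  }
  patient_profile(vals[1L], vals[2L])
}

#' Serialize a configuration back to YAML
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A YAML string in canonical (default-ordered) key order.
#' @export
dump_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::as.yaml(unclass(cfg))
}

#' Hash of the canonicalized configuration
#'
#' MD5 digest over the canonical YAML serialization (stable key order), so
#' two configurations hash equal exactly when every non-cosmetic key is
#' equal.  Used for output provenance.
#'
#' @param cfg A `run_config`.
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  txt <- dump_config(cfg)
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

# Build typed parameter objects from a validated config.
.lipid_from_config <- function(cfg) {
  l <- cfg$lipid
  lipid_params(beta = l$beta, theta = l$theta, band_energy = l$band_energy,
               observable_scale = l$observable_scale, hdl_sign = l$hdl_sign,
               ox0 = l$ox0, normalization = l$normalization)
}

.plaque_from_config <- function(cfg) {
  p <- cfg$plaque
  plaque_params(k1 = p$k1, area = p$area, ox_level = p$ox_level,
                deposit_mass = p$deposit_mass, h0 = p$h0,
                artery_length = p$artery_length, band_energy = p$band_energy,
                observable_scale = p$observable_scale)
}
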