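#' Write simulation or sweep outputs with a provenance sidecar
#'
#' Writes the result of [simulate_patient()], [simulate_plaque()] or
#' [gamma_sweep()] as a CSV (header row, dot decimal, LF line endings) plus
#' a JSON sidecar carrying the full parameter echo, package version,
#' configuration hash, and a note for every reconstructed modelling choice
#' in effect (HDL channel sign, toxic-surrogate constants), so outputs are
#' self-describing.  A `created` timestamp is written to the sidecar but is
#' excluded from the hashed content; re-running the same configuration
#' reproduces every other byte.
#'
#' @param result A `lipid_sim`, `plaque_sim` or `sweep_result` object.
#' @param out_dir Output directory (created if absent).
#' @param cfg Optional `run_config`; when given, its hash and echo go into
#'   the sidecar.
#' @param prefix File name stem (default derived from the result class).
#' @return Named character vector of the files written (`csv`, `json`),
#'   invisibly.
#' @export
write_outputs <- function(result, out_dir, cfg = NULL, prefix = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  if (!is.null(cfg)) stopifnot(inherits(cfg, "run_config"))

  if (inherits(result, "lipid_sim")) {
    if (is.null(prefix)) prefix <- "lipid"
    tab <- cbind(result$trajectory, MDA = result$mda)
    names(tab) <- c("t", "HDL", "Ox", "LDL", "MDA")
    meta <- list(
      kind = "lipid_sim",
      profile = list(ldl = result$profile$ldl, hdl = result$profile$hdl,
                     label = result$profile$label),
      order = result$order, t_end = result$t_end, step = result$step,
      params = unclass(result$params),
      peak = result$peak
    )
  } else if (inherits(result, "plaque_sim")) {
    if (is.null(prefix)) prefix <- "plaque"
    tab <- data.frame(t = result$times, h = result$h_series,
                      mineral = result$mineral_series)
    meta <- list(
      kind = "plaque_sim",
      order = result$order, t_end = result$t_end, step = result$step,
      coupled = result$coupled,
      params = unclass(result$params)
    )
  } else if (inherits(result, "sweep_result")) {
    if (is.null(prefix)) prefix <- "sweep"
    tab <- hysteresis_report(result)
    meta <- list(
      kind = "sweep_result",
      model = result$model,
      profile = list(ldl = result$profile$ldl, hdl = result$profile$hdl,
                     label = result$profile$label),
      grid = result$gamma_grid,
      peaks = result$peak_values,
      raw_peaks = result$raw_peaks,
      peak_times = result$peak_times,
      reversal_gamma = result$reversal_gamma,
      transform_enabled = result$transform_enabled,
      gamma_c = result$gamma_c, c_tox = result$c_tox,
      t_end = result$t_end, step = result$step
    )
  } else {
    stop("unsupported result class: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }

  meta$software <- list(
    package = "statinfde",
    version = as.character(utils::packageVersion("statinfde"))
  )
  meta$reconstructions <- .reconstruction_notes(result)
  if (!is.null(cfg)) {
    meta$config <- unclass(cfg)
    meta$config_hash <- config_hash(cfg)
  }

  csv_path <- file.path(out_dir, paste0(prefix, ".csv"))
  json_path <- file.path(out_dir, paste0(prefix, ".json"))
  con <- tryCatch(file(csv_path, "wb"), error = function(e) {
    stop("cannot write to path: ", csv_path, call. = FALSE)
  })
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)

  # timestamp added after hashing-relevant content is fixed
  meta$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(c(csv = csv_path, json = json_path))
}

.reconstruction_notes <- function(result) {
  notes <- list()
  if (inherits(result, "lipid_sim")) {
    notes$hdl_channel_sign <- list(
      value = result$params$hdl_sign,
      note = paste("sign of the HDL equation's beta*HDL*LDL term;",
                   "-1 encodes the protective (depleting) role of HDL")
    )
    notes$mda_observable <- paste(
      "MDA(t) = observable_scale * band_energy * Ox(t) * LDL(t);",
      "a defined observable, not a fitted assay curve")
  }
  if (inherits(result, "sweep_result") && result$transform_enabled) {
    notes$toxic_surrogate <- list(
      gamma_c = result$gamma_c, c_tox = result$c_tox,
      note = paste("composite response R = peak * (1 + c_tox * max(0,",
                   "1/gamma_c - 1/gamma)); calibrated surrogate for the",
                   "toxic 1/gamma reading of the dose indicator")
    )
  }
  notes
}
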