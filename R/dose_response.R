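#' Sweep the fractional order as a statin-dose indicator
#'
#' Runs the lipid (or plaque) simulation across a grid of fractional orders
#' gamma in (0, 1) - the model's statin concentration indicator - and
#' records the peak of the peroxidation observable at each order.  In the
#' therapeutic regime a higher gamma (more statin) lowers and delays the
#' peak.  When `transform = TRUE` the toxic reading of the dose, 1/gamma,
#' is folded in through the composite response
#' \deqn{R(\gamma) = peak(\gamma)\,\bigl(1 + c_{tox}\,\max(0, 1/\gamma_c -
#'   1/\gamma)\bigr),}
#' which leaves the response untouched below the toxicity threshold
#' `gamma_c` and penalizes it increasingly above, producing the
#' non-monotonic reversal of the dose-response curve.  The surrogate
#' constants `gamma_c` and `c_tox` are a shipped calibration (see the
#' methods vignette), not quantities derived from first principles.
#'
#' @param gamma_grid Strictly increasing vector of orders in (0, 1).
#' @param model `"lipid"` (default) or `"plaque"`; selects which
#'   observable's peak is recorded (MDA, or the mineralization observable
#'   of a coupled run driven by the lipid Ox series).
#' @param profile A [patient_profile()] (default 160:50).
#' @param lipid A [lipid_params()] object.
#' @param plaque A [plaque_params()] object (used when `model = "plaque"`).
#' @param t_end,step Simulation grid (defaults 6, 0.01).
#' @param transform Logical; apply the toxic 1/gamma composite response.
#' @param gamma_c Toxicity threshold order (default 0.70).
#' @param c_tox Toxicity strength (default 0.03); `0` disables the penalty
#'   even when `transform = TRUE`.
#' @return An object of class `sweep_result`: list with `gamma_grid`,
#'   `peak_values` (composite response when transformed), `raw_peaks`,
#'   `peak_times`, `toxicity_index` (= 1/gamma), `reversal_gamma` (`NA` if
#'   no reversal), `transform_enabled`, `failed` (logical per grid point),
#'   and the parameter echo.
#' @seealso [find_reversal()], [hysteresis_report()]
#' @export
gamma_sweep <- function(gamma_grid, model = c("lipid", "plaque"),
                        profile = patient_profile(160, 50),
                        lipid = lipid_params(), plaque = plaque_params(),
                        t_end = 6, step = 0.01, transform = FALSE,
                        gamma_c = 0.70, c_tox = 0.03) {
  model <- match.arg(model)
  if (length(gamma_grid) < 1L || any(!is.finite(gamma_grid)) ||
      any(gamma_grid <= 0) || any(gamma_grid >= 1)) {
    stop("`gamma_grid` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.unsorted(gamma_grid, strictly = TRUE)) {
    stop("`gamma_grid` must be strictly increasing", call. = FALSE)
  }
  n <- length(gamma_grid)
  raw <- numeric(n); ptime <- numeric(n); failed <- logical(n)
  for (i in seq_len(n)) {
    g <- gamma_grid[i]
    res <- tryCatch({
      sim <- simulate_patient(profile, lipid, order = g,
                              t_end = t_end, step = step)
      if (model == "plaque") {
        ps <- simulate_plaque(plaque, order = g, t_end = t_end, step = step,
                              ox_series = sim$trajectory$Ox)
        pk <- peak_metrics(ps$mineral_series, ps$times)
      } else {
        pk <- sim$peak
      }
      c(pk$peak_value, pk$peak_time)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed[i] <- TRUE
      raw[i] <- NA_real_; ptime[i] <- NA_real_
    } else {
      raw[i] <- res[1L]; ptime[i] <- res[2L]
    }
  }
  peaks <- raw
  if (isTRUE(transform)) {
    penalty <- 1 + c_tox * pmax(0, 1 / gamma_c - 1 / gamma_grid)
    peaks <- raw * penalty
  }
  ok <- !failed
  rev_g <- if (sum(ok) >= 2L) find_reversal(peaks[ok], gamma_grid[ok]) else NA_real_
  structure(
    list(gamma_grid = gamma_grid, peak_values = peaks, raw_peaks = raw,
         peak_times = ptime, toxicity_index = 1 / gamma_grid,
         reversal_gamma = rev_g, transform_enabled = isTRUE(transform),
         failed = failed, model = model, profile = profile,
         gamma_c = gamma_c, c_tox = if (isTRUE(transform)) c_tox else NA_real_,
         t_end = t_end, step = step),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Dose-response sweep (", x$model, " model): ",
      length(x$gamma_grid), " orders in [",
      min(x$gamma_grid), ", ", max(x$gamma_grid), "], toxic transform ",
      if (x$transform_enabled) "on" else "off", "\n", sep = "")
  if (is.na(x$reversal_gamma)) {
    cat("  no reversal detected (monotone response)\n")
  } else {
    cat("  reversal at gamma =", x$reversal_gamma, "\n")
  }
  invisible(x)
}

#' Detect the toxic reversal point of a dose-response curve
#'
#' Scans the peak response along increasing gamma and returns the smallest
#' gamma at which the response strictly increases relative to the previous
#' grid point, after it has strictly decreased at least once.  Comparisons
#' use a relative tolerance of 1e-9 so floating noise below that level
#' neither creates nor hides a reversal; plateaus do not trigger.
#'
#' @param peak_values Numeric response values.
#' @param gamma_grid Matching gamma grid (length >= 2).
#' @return The reversal gamma, or `NA_real_` if the sequence is monotone
#'   non-increasing.
#' @examples
#' find_reversal(c(5, 4, 3, 3.5), c(0.2, 0.4, 0.6, 0.8))  # 0.8
#' find_reversal(c(5, 4, 3, 2), c(0.2, 0.4, 0.6, 0.8))    # NA
#' @export
find_reversal <- function(peak_values, gamma_grid) {
  if (length(peak_values) != length(gamma_grid)) {
    stop("`peak_values` and `gamma_grid` must have equal length",
         call. = FALSE)
  }
  if (length(peak_values) < 2L) return(NA_real_)
  eps <- 1e-9
  decreased <- FALSE
  for (i in 2:length(peak_values)) {
    prev <- peak_values[i - 1L]
    cur <- peak_values[i]
    tol <- eps * max(abs(prev), abs(cur), 1e-300)
    if (cur < prev - tol) {
      decreased <- TRUE
    } else if (decreased && cur > prev + tol) {
      return(gamma_grid[i])
    }
  }
  NA_real_
}

#' Per-order hysteresis table of a sweep
#'
#' Tabulates, for each order in a completed sweep, the toxicity index
#' 1/gamma, the peak response and its time, and the delay of the peak
#' relative to the largest order in the grid (the rightward peak shift
#' that signals treatment-induced hysteresis).
#'
#' @param sweep A `sweep_result` from [gamma_sweep()].
#' @return A data frame with columns `gamma`, `toxicity_index`,
#'   `peak_value`, `peak_time`, `delta_peak_time`.
#' @export
hysteresis_report <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  n <- length(sweep$gamma_grid)
  if (n == 0L) {
    return(data.frame(gamma = numeric(0), toxicity_index = numeric(0),
                      peak_value = numeric(0), peak_time = numeric(0),
                      delta_peak_time = numeric(0)))
  }
  ref_time <- sweep$peak_times[n]
  data.frame(
    gamma = sweep$gamma_grid,
    toxicity_index = sweep$toxicity_index,
    peak_value = sweep$peak_values,
    peak_time = sweep$peak_times,
    delta_peak_time = sweep$peak_times - ref_time
  )
}
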