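#' Parameters of the coupled HDL/oxidative-stress/LDL system
#'
#' @param beta Plaque-accumulation rate constant (1/time per concentration
#'   unit); scales how fast lipoprotein interactions feed plaque components.
#' @param theta Oxidative-stress coupling fraction in `[0, 1]`; splits the
#'   beta-driven flux between the HDL-mediated quenching of oxidative
#'   stress (`theta`) and direct LDL growth (`1 - theta`).
#' @param band_energy Molar bond energy (kcal/mol) weighting the
#'   peroxidation observable; default 4.98, the aldehyde (CHO) stretch at
#'   1744 cm^-1 that tracks malondialdehyde.
#' @param observable_scale Positive scale mapping the state product to the
#'   reported observable's arbitrary units.
#' @param hdl_sign Sign of the HDL channel, +1 or -1 (default -1 so that
#'   LDL depletes HDL, its protective role; see the methods vignette for
#'   why this sign is exposed as a parameter).
#' @param ox0 Initial oxidative-stress level Ox(0) (arbitrary units).
#' @param normalization Serum concentrations (mg/dL) are divided by this
#'   value to form dimensionless initial states (default 100).
#' @return An object of class `lipid_params`.
#' @export
lipid_params <- function(beta = 0.2, theta = 0.7, band_energy = 4.98,
                         observable_scale = 1, hdl_sign = -1, ox0 = 8,
                         normalization = 100) {
  if (!is.numeric(theta) || theta < 0 || theta > 1) {
    stop("`theta` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(band_energy) || band_energy <= 0) {
    stop("`band_energy` must be positive", call. = FALSE)
  }
  if (!is.numeric(observable_scale) || observable_scale <= 0) {
    stop("`observable_scale` must be positive", call. = FALSE)
  }
  if (!hdl_sign %in% c(-1, 1)) {
    stop("`hdl_sign` must be +1 or -1", call. = FALSE)
  }
  if (!is.numeric(ox0) || ox0 < 0) {
    stop("`ox0` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(normalization) || normalization <= 0) {
    stop("`normalization` must be positive", call. = FALSE)
  }
  structure(
    list(beta = beta, theta = theta, band_energy = band_energy,
         observable_scale = observable_scale, hdl_sign = hdl_sign,
         ox0 = ox0, normalization = normalization),
    class = "lipid_params"
  )
}

#' A patient's serum lipoprotein profile
#'
#' @param ldl Serum LDL concentration, mg/dL (> 0).
#' @param hdl Serum HDL concentration, mg/dL (> 0).
#' @param label Free-text label; defaults to "LDL:HDL".
#' @return An object of class `patient_profile`.
#' @examples
#' patient_profile(160, 50)
#' @export
patient_profile <- function(ldl, hdl, label = NULL) {
  if (!is.numeric(ldl) || ldl <= 0 || !is.numeric(hdl) || hdl <= 0) {
    stop("`ldl` and `hdl` must be positive (mg/dL)", call. = FALSE)
  }
  if (is.null(label)) label <- paste0(format(ldl), ":", format(hdl))
  structure(list(ldl = ldl, hdl = hdl, label = label),
            class = "patient_profile")
}

#' Right-hand side of the coupled lipoprotein system
#'
#' The state is `(HDL, Ox, LDL)` and the Caputo-fractional system reads
#' \deqn{D^\gamma HDL = s_h\, \beta\, HDL\, LDL}
#' \deqn{D^\gamma Ox  = -\theta \beta\, HDL\, Ox - Ox}
#' \deqn{D^\gamma LDL = (1 - \theta) \beta\, LDL + Ox}
#' with `s_h` the configurable HDL-channel sign.  Pure function of
#' `(state, params)`; `t` is accepted for the solver interface but unused.
#'
#' @param t Time (unused; autonomous system).
#' @param state Numeric length-3 vector `(HDL, Ox, LDL)`.
#' @param params A [lipid_params()] object.
#' @return Numeric length-3 derivative vector.
#' @export
lipid_rhs <- function(t, state, params) {
  stopifnot(inherits(params, "lipid_params"))
  hdl <- state[1L]; ox <- state[2L]; ldl <- state[3L]
  c(
    params$hdl_sign * params$beta * hdl * ldl,
    -params$theta * params$beta * hdl * ox - ox,
    (1 - params$theta) * params$beta * ldl + ox
  )
}

#' Simulate lipid peroxidation for one patient profile
#'
#' Solves the coupled HDL/Ox/LDL system from the patient's serum profile
#' (initial HDL and LDL are the serum values divided by
#' `params$normalization`; Ox(0) is `params$ox0`) and forms the
#' malondialdehyde observable
#' \deqn{MDA(t) = scale \cdot E_{band} \cdot Ox(t) \cdot LDL(t),}
#' the band-energy-weighted product of oxidative stress and its LDL
#' substrate, in arbitrary units.  Time is in the model's arbitrary units.
#'
#' @param profile A [patient_profile()].
#' @param params A [lipid_params()] object.
#' @param order Fractional order gamma in (0, 1]; interpreted as the statin
#'   concentration indicator.
#' @param t_end,step Uniform grid specification (defaults 6 and 0.01).
#' @param corrector_iterations Passed to [solve_fde()].
#' @return An object of class `lipid_sim`: list with `trajectory` (data
#'   frame `t`, `HDL`, `Ox`, `LDL`), `mda` (observable series), `profile`,
#'   `params`, `order`, and `peak` ([peak_metrics()] of the MDA series).
#' @examples
#' sim <- simulate_patient(patient_profile(160, 50), lipid_params(), 0.8)
#' sim$peak
#' @export
simulate_patient <- function(profile, params = lipid_params(), order = 0.8,
                             t_end = 6, step = 0.01,
                             corrector_iterations = 1L) {
  stopifnot(inherits(profile, "patient_profile"),
            inherits(params, "lipid_params"))
  if (order <= 0 || order > 1) {
    stop("therapeutic simulations require `order` in (0, 1]", call. = FALSE)
  }
  y0 <- c(profile$hdl, params$ox0 * params$normalization,
          profile$ldl) / params$normalization
  prob <- fde_problem(order, function(t, y) lipid_rhs(t, y, params),
                      y0, t_end, step)
  tr <- tryCatch(
    solve_fde(prob, corrector_iterations = corrector_iterations),
    error = function(e) {
      stop("simulate_patient [", profile$label, "]: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  traj <- data.frame(t = tr$times, HDL = tr$states[, 1L],
                     Ox = tr$states[, 2L], LDL = tr$states[, 3L])
  mda <- params$observable_scale * params$band_energy * traj$Ox * traj$LDL
  structure(
    list(trajectory = traj, mda = mda, profile = profile, params = params,
         order = order, t_end = t_end, step = step,
         peak = peak_metrics(mda, traj$t)),
    class = "lipid_sim"
  )
}

#' @export
print.lipid_sim <- function(x, ...) {
  cat("Lipid peroxidation simulation - profile", x$profile$label,
      "- order", x$order, "\n")
  cat(sprintf("  peak MDA %.4g at t = %.3g (%s)\n", x$peak$peak_value,
              x$peak$peak_time,
              if (x$peak$is_interior_peak) "interior" else "boundary"))
  invisible(x)
}

#' Peak metrics of an observable series
#'
#' Locates the maximum of a series on its time grid.  Ties are broken by
#' the earliest time; a maximum attained at the first or last node is
#' flagged as a boundary (non-interior) peak.
#'
#' @param values Numeric series (non-empty).
#' @param times Matching time grid.
#' @return List with `peak_value`, `peak_time`, `is_interior_peak`.
#' @examples
#' peak_metrics(c(0, 2, 1), c(0, 1, 2))
#' @export
peak_metrics <- function(values, times) {
  if (length(values) == 0L) {
    stop("`values` must be non-empty", call. = FALSE)
  }
  if (length(values) != length(times)) {
    stop("`values` and `times` must have equal length", call. = FALSE)
  }
  i <- which.max(values)   # first index of the maximum: earliest-time tie-break
  list(
    peak_value = values[i],
    peak_time = times[i],
    is_interior_peak = (i > 1L && i < length(values))
  )
}
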