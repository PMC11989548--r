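#' Parameters of the arterial wall deformation (plaque growth) model
#'
#' The plaque model reduces a tube-domain deposition balance to a single
#' scalar equation for the wall deformation h(t):
#' \deqn{D^\gamma h = \frac{k_1}{A}\, h\, Ox\, M,}
#' with k1 the LDL formation rate, A the lesion area, Ox the peroxidation
#' product level and M the total atheromatic deposit mass.  The deposition
#' speed u = dh/dt of the underlying derivation is recovered by
#' [integrate_velocity_check()].
#'
#' @param k1 Rate of LDL formation (>= 0; zero freezes the wall).
#' @param area Artery lesion area A (> 0).
#' @param ox_level Constant peroxidation product level Ox (>= 0); ignored
#'   when a coupled Ox series is supplied to [simulate_plaque()].
#' @param deposit_mass Total atheromatic deposit mass M (>= 0).
#' @param h0 Initial wall deformation (> 0).
#' @param artery_length Artery length L in cm (> 0; geometric metadata).
#' @param band_energy Molar bond energy (kcal/mol) weighting the
#'   mineralization observable; default 2.79, the phosphate PO4(3-) stretch
#'   at 976 cm^-1 that tracks hydroxyapatite-like mineral.
#' @param observable_scale Positive scale for the observable.
#' @return An object of class `plaque_params`.
#' @export
plaque_params <- function(k1 = 0.3, area = 1, ox_level = 1, deposit_mass = 1,
                          h0 = 0.1, artery_length = 5, band_energy = 2.79,
                          observable_scale = 1) {
  pos <- c(area = area, h0 = h0, artery_length = artery_length,
           band_energy = band_energy, observable_scale = observable_scale)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("area, h0, artery_length, band_energy, observable_scale ",
         "must be strictly positive", call. = FALSE)
  }
  if (!is.finite(k1) || k1 < 0 || ox_level < 0 || deposit_mass < 0) {
    stop("`k1`, `ox_level` and `deposit_mass` must be non-negative",
         call. = FALSE)
  }
  structure(
    list(k1 = k1, area = area, ox_level = ox_level,
         deposit_mass = deposit_mass, h0 = h0,
         artery_length = artery_length, band_energy = band_energy,
         observable_scale = observable_scale),
    class = "plaque_params"
  )
}

#' Right-hand side of the wall deformation equation
#'
#' Returns \eqn{(k_1/A)\, h\, Ox\, M}: linear in the deformation h, driven
#' by the oxidized product level and the deposited mass.
#'
#' @param t Time (unused; the equation is autonomous in constant-Ox mode).
#' @param h Wall deformation (scalar).
#' @param params A [plaque_params()] object.
#' @param ox Oxidized product level; defaults to `params$ox_level`.
#' @return Scalar derivative.
#' @examples
#' plaque_rhs(0, 2, plaque_params(k1 = 1, area = 4, ox_level = 3,
#'                                deposit_mass = 1))  # 1.5
#' @export
plaque_rhs <- function(t, h, params, ox = params$ox_level) {
  stopifnot(inherits(params, "plaque_params"))
  (params$k1 / params$area) * h * ox * params$deposit_mass
}

#' Simulate arterial wall deformation and the mineralization observable
#'
#' Solves the deformation equation with the fractional PECE solver.  In
#' constant-Ox mode (the default) the exact solution is the Mittag-Leffler
#' form \eqn{h(t) = h_0 E_\gamma((k_1/A)\,Ox\,M\, t^\gamma)}, which serves
#' as the solver oracle.  In coupled mode an oxidative-stress series from a
#' lipid simulation on the same grid drives the growth, and the
#' mineralization observable is
#' \deqn{mineral(t) = scale \cdot E_{976} \cdot Ox(t) \cdot h(t).}
#' In constant-Ox mode the observable uses the constant `ox_level`.
#'
#' @param params A [plaque_params()] object.
#' @param order Fractional order gamma in (0, 2] (orders above 1 arise only
#'   through the toxic 1/gamma reading of the dose indicator).
#' @param t_end,step Uniform grid specification (defaults 6 and 0.01).
#' @param ox_series Optional numeric vector of Ox values at the grid nodes
#'   (length `t_end/step + 1`), typically `sim$trajectory$Ox` from
#'   [simulate_patient()] run on the identical grid.
#' @param corrector_iterations Passed to [solve_fde()].
#' @return An object of class `plaque_sim`: list with `times`, `h_series`,
#'   `mineral_series`, `params`, `order`.
#' @export
simulate_plaque <- function(params = plaque_params(), order = 0.9,
                            t_end = 6, step = 0.01, ox_series = NULL,
                            corrector_iterations = 1L) {
  stopifnot(inherits(params, "plaque_params"))
  if (order <= 0 || order > 2) {
    stop("`order` must lie in (0, 2]", call. = FALSE)
  }
  n_nodes <- round(t_end / step) + 1L
  if (!is.null(ox_series)) {
    if (length(ox_series) != n_nodes || any(!is.finite(ox_series))) {
      stop("`ox_series` must be finite with one value per grid node (",
           n_nodes, "); rerun the lipid model on the same grid",
           call. = FALSE)
    }
    # Piecewise-linear interpolant: the corrector evaluates at grid nodes,
    # but predictor states are requested at t_{n+1} too, so index by time.
    grid_t <- seq(0, t_end, by = step)
    ox_at <- stats::approxfun(grid_t, ox_series, rule = 2)
    rhs <- function(t, h) plaque_rhs(t, h, params, ox = ox_at(t))
  } else {
    rhs <- function(t, h) plaque_rhs(t, h, params)
  }
  prob <- fde_problem(order, rhs, params$h0, t_end, step)
  tr <- solve_fde(prob, corrector_iterations = corrector_iterations)
  h_series <- tr$states[, 1L]
  ox_obs <- if (is.null(ox_series)) rep(params$ox_level, n_nodes) else ox_series
  mineral <- params$observable_scale * params$band_energy * ox_obs * h_series
  structure(
    list(times = tr$times, h_series = h_series, mineral_series = mineral,
         params = params, order = order, t_end = t_end, step = step,
         coupled = !is.null(ox_series)),
    class = "plaque_sim"
  )
}

#' @export
print.plaque_sim <- function(x, ...) {
  cat("Plaque growth simulation - order", x$order,
      if (x$coupled) "- coupled Ox drive" else "- constant Ox", "\n")
  cat(sprintf("  h(0) = %.4g -> h(T) = %.4g on [0, %g]\n",
              x$h_series[1L], x$h_series[length(x$h_series)], x$t_end))
  invisible(x)
}

#' Consistency of the solved deformation with the deposition-speed relation
#'
#' The tube-domain derivation behind the plaque equation identifies the
#' deposition speed with the deformation rate, u = dh/dt.  For a classical
#' (order 1) constant-Ox run this checks that the centered finite
#' difference of the solved h matches the right-hand side at interior
#' nodes; the residual must shrink linearly with the step.
#'
#' @param params A [plaque_params()] object.
#' @param t_end,step Grid used for the order-1 solve.
#' @return List with `residual` (max absolute mismatch over interior
#'   nodes), `rhs_scale` (max |rhs| for relative comparison), and `step`.
#' @export
integrate_velocity_check <- function(params = plaque_params(), t_end = 1,
                                     step = 1e-3) {
  sim <- simulate_plaque(params, order = 1, t_end = t_end, step = step)
  h <- sim$h_series
  t <- sim$times
  n <- length(h)
  if (n < 3L) stop("grid too coarse for a finite-difference check",
                   call. = FALSE)
  interior <- 2:(n - 1L)
  dh <- (h[interior + 1L] - h[interior - 1L]) / (2 * step)
  rhs_vals <- vapply(interior, function(i) plaque_rhs(t[i], h[i], params),
                     numeric(1))
  list(residual = max(abs(dh - rhs_vals)),
       rhs_scale = max(abs(rhs_vals), 1e-300),
       step = step)
}

#' Time at which a series reaches the midpoint of its total rise
#'
#' Used to place a monotone (boundary-peaked) observable in time: returns
#' the first grid time at which the series crosses halfway between its
#' initial and maximal values.  For a series with an interior peak the
#' peak time itself (from [peak_metrics()]) is the better summary.
#'
#' @param values Numeric series.
#' @param times Matching time grid.
#' @return First time of crossing; `NA` if the series never rises.
#' @export
half_rise_time <- function(values, times) {
  if (length(values) != length(times) || length(values) == 0L) {
    stop("`values` and `times` must be non-empty and of equal length",
         call. = FALSE)
  }
  lo <- values[1L]
  hi <- max(values)
  if (hi <= lo) return(NA_real_)
  mid <- (lo + hi) / 2
  times[which(values >= mid)[1L]]
}
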