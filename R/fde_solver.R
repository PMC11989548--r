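#' Define a Caputo fractional initial-value problem
#'
#' Packages the order, right-hand side, initial state and uniform time grid
#' of a Caputo fractional differential equation
#' \eqn{D^\gamma y(t) = f(t, y(t))}, \eqn{y(0) = y_0}, to be solved by
#' [solve_fde()].  Initial conditions are stated in ordinary (integer)
#' derivatives, as is characteristic of the Caputo operator: for orders in
#' (1, 2] a second condition, the initial slope \eqn{y'(0)}, is required
#' (it defaults to zero).
#'
#' @param order Fractional order gamma, real in (0, 2].
#' @param rhs Function `(t, y) -> dy`, returning a numeric vector of the
#'   same length as `y`.
#' @param initial_state Numeric vector y(0).
#' @param t_end Final time T > 0.
#' @param step Grid step k > 0; `t_end / step` must be a whole number of
#'   steps (a deviation below 1e-9 relative is rounded with a warning).
#' @param initial_slope Numeric vector y'(0); used only when `order > 1`.
#' @return An object of class `fde_problem`.
#' @seealso [solve_fde()], [mittag_leffler()]
#' @export
fde_problem <- function(order, rhs, initial_state, t_end, step,
                        initial_slope = NULL) {
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order) ||
      order <= 0 || order > 2) {
    stop("`order` must be a single real in (0, 2]", call. = FALSE)
  }
  stopifnot(is.function(rhs))
  if (!is.numeric(initial_state) || length(initial_state) < 1L ||
      any(!is.finite(initial_state))) {
    stop("`initial_state` must be a finite numeric vector", call. = FALSE)
  }
  if (!is.numeric(t_end) || t_end <= 0 || !is.numeric(step) || step <= 0) {
    stop("`t_end` and `step` must be positive", call. = FALSE)
  }
  ratio <- t_end / step
  n_steps <- round(ratio)
  if (n_steps < 1L || abs(ratio - n_steps) > 1e-9 * max(1, n_steps)) {
    stop("`t_end` must be a whole multiple of `step`", call. = FALSE)
  }
  if (abs(ratio - n_steps) > 0) {
    warning("t_end/step off a whole count by < 1e-9; rounding to ",
            n_steps, " steps", call. = FALSE)
  }
  dim <- length(initial_state)
  if (order > 1) {
    if (is.null(initial_slope)) initial_slope <- numeric(dim)
    if (length(initial_slope) != dim || any(!is.finite(initial_slope))) {
      stop("`initial_slope` must be finite and match `initial_state`",
           call. = FALSE)
    }
  } else {
    initial_slope <- NULL
  }
  structure(
    list(order = order, rhs = rhs, initial_state = initial_state,
         initial_slope = initial_slope, t_end = t_end, step = step,
         n_steps = as.integer(n_steps), dimension = dim),
    class = "fde_problem"
  )
}

#' Solve a Caputo fractional IVP with the fractional Adams PECE scheme
#'
#' Predictor-corrector (PECE) fractional Adams-Bashforth-Moulton method:
#' the predictor is the product rectangle (fractional Euler) rule with
#' weights
#' \deqn{b_{j,n+1} = (n+1-j)^\gamma - (n-j)^\gamma}
#' scaled by \eqn{h^\gamma/\Gamma(\gamma+1)}, and the corrector is the
#' product trapezoidal rule with weights built from \eqn{(\cdot)^{\gamma+1}}
#' differences scaled by \eqn{h^\gamma/\Gamma(\gamma+2)}.  After each
#' correction the right-hand side is re-evaluated at the corrected value
#' (the final E of PECE) and stored in the history.  At `order = 1` the
#' weights collapse to the classical composite Euler predictor and
#' trapezoidal corrector.
#'
#' The history sums make the cost quadratic in the number of steps; grids
#' up to ~1e4 nodes are comfortable.
#'
#' @param problem An [fde_problem()].
#' @param corrector_iterations Number of correct-evaluate passes per step
#'   (default 1; more passes tighten the implicit trapezoidal solve).
#' @return An object of class `fde_trajectory`: list with `times` (length
#'   n+1), `states` ((n+1) x d matrix, first row the initial state), and
#'   `order`.
#' @examples
#' p <- fde_problem(0.8, function(t, y) -y, 1, t_end = 1, step = 0.01)
#' tr <- solve_fde(p)
#' tail(tr$states[, 1], 1)          # ~ E_0.8(-1)
#' mittag_leffler(0.8, -1)
#' @export
solve_fde <- function(problem, corrector_iterations = 1L) {
  stopifnot(inherits(problem, "fde_problem"))
  corrector_iterations <- as.integer(corrector_iterations)
  if (corrector_iterations < 1L) {
    stop("`corrector_iterations` must be >= 1", call. = FALSE)
  }
  g <- problem$order
  h <- problem$step
  n_steps <- problem$n_steps
  d <- problem$dimension
  rhs <- problem$rhs
  times <- h * (0:n_steps)

  # Taylor polynomial of the initial conditions (Caputo: ordinary ICs)
  taylor <- function(t) {
    if (g > 1) problem$initial_state + t * problem$initial_slope
    else problem$initial_state
  }

  pow_g <- (0:(n_steps + 1))^g        # m^gamma,     index m+1
  pow_g1 <- (0:(n_steps + 1))^(g + 1) # m^(gamma+1), index m+1
  cp <- h^g / gamma(g + 1)            # predictor scale
  cc <- h^g / gamma(g + 2)            # corrector scale

  states <- matrix(NA_real_, n_steps + 1L, d)
  fhist <- matrix(NA_real_, n_steps + 1L, d)
  states[1L, ] <- problem$initial_state
  f0 <- rhs(times[1L], problem$initial_state)
  .check_f(f0, d, 0L)
  fhist[1L, ] <- f0

  for (n in 0:(n_steps - 1L)) {
    tn1 <- times[n + 2L]
    tay <- taylor(tn1)
    hist <- fhist[seq_len(n + 1L), , drop = FALSE]

    # predictor weights b_j = (n+1-j)^g - (n-j)^g, j = 0..n
    j <- 0:n
    b <- pow_g[n + 2L - j] - pow_g[n + 1L - j]
    y_pred <- tay + cp * as.vector(crossprod(hist, b))

    # corrector weights a_j, j = 0..n, plus weight 1 on the new node
    a <- numeric(n + 1L)
    a[1L] <- pow_g1[n + 1L] - (n - g) * pow_g[n + 2L]
    if (n >= 1L) {
      jj <- 1:n
      a[jj + 1L] <- pow_g1[n - jj + 3L] + pow_g1[n - jj + 1L] -
        2 * pow_g1[n - jj + 2L]
    }
    mem <- as.vector(crossprod(hist, a))

    y_new <- y_pred
    f_new <- rhs(tn1, y_new)
    .check_f(f_new, d, n + 1L)
    for (it in seq_len(corrector_iterations)) {
      y_new <- tay + cc * (mem + f_new)
      if (any(!is.finite(y_new))) {
        stop("solve_fde: non-finite state at step ", n + 1L, call. = FALSE)
      }
      f_new <- rhs(tn1, y_new)
      .check_f(f_new, d, n + 1L)
    }
    states[n + 2L, ] <- y_new
    fhist[n + 2L, ] <- f_new
  }

  structure(
    list(times = times, states = states, order = g,
         step = h, dimension = d),
    class = "fde_trajectory"
  )
}

.check_f <- function(f, d, step_index) {
  if (length(f) != d || any(!is.finite(f))) {
    stop("solve_fde: right-hand side returned a non-finite or wrongly ",
         "sized value at step ", step_index, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
as.data.frame.fde_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  df <- data.frame(t = x$times, x$states)
  names(df) <- c("t", paste0("y", seq_len(x$dimension)))
  df
}

#' @export
print.fde_trajectory <- function(x, ...) {
  cat("Caputo FDE trajectory: order", x$order, "-",
      length(x$times), "nodes on [0,", max(x$times), "] -",
      x$dimension, "state component(s)\n")
  invisible(x)
}

#' Empirical convergence order of the PECE scheme
#'
#' Solves the same problem on a sequence of step sizes, measures the error
#' at the final time against a closed-form reference, and returns the least
#' squares slope of log(error) against log(step).  For smooth problems the
#' fractional Adams PECE scheme converges with order min(2, 1 + gamma).
#'
#' @param problem An [fde_problem()]; its `step` field is overridden by
#'   each member of `steps`.
#' @param steps Numeric vector of at least 3 step sizes, each dividing
#'   `problem$t_end` evenly.
#' @param reference Function `t -> y(t)` giving the exact solution
#'   (vector-valued to match the problem dimension).
#' @return A list with `slope` (the fitted order; `NA` when the fit is
#'   degenerate), `errors`, `steps`, and `degenerate` (`TRUE` when all
#'   errors are at rounding level, e.g. for a zero right-hand side).
#' @export
empirical_order <- function(problem, steps, reference) {
  stopifnot(inherits(problem, "fde_problem"), is.function(reference))
  if (length(steps) < 3L) {
    stop("`steps` must contain at least 3 step sizes", call. = FALSE)
  }
  errs <- vapply(steps, function(h) {
    p <- fde_problem(problem$order, problem$rhs, problem$initial_state,
                     problem$t_end, h, problem$initial_slope)
    tr <- solve_fde(p)
    yT <- tr$states[nrow(tr$states), ]
    max(abs(yT - reference(problem$t_end)))
  }, numeric(1))
  if (all(errs < 1e-13)) {
    return(list(slope = NA_real_, errors = errs, steps = steps,
                degenerate = TRUE))
  }
  fit <- stats::lm(log(errs) ~ log(steps))
  list(slope = unname(stats::coef(fit)[2L]), errors = errs, steps = steps,
       degenerate = FALSE)
}
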