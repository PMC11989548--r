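# Independent oracles used across the suite.

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# E_{1/2}(z) = exp(z^2) * erfc(-z), closed form for order one-half.
ml_half_closed <- function(z) exp(z^2) * erfc(-z)

# Truncated power series with explicit term count; independent of the
# package's ratio-accumulated series (direct gamma() calls).
ml_series_direct <- function(alpha, z, n_terms = 200L) {
  j <- 0:(n_terms - 1L)
  sum(z^j / gamma(alpha * j + 1))
}

# Classical Adams-Bashforth-Moulton PECE written over the whole interval
# (cumulative quadrature form): Euler predictor from t = 0, composite
# trapezoidal corrector, right-hand side re-evaluated at the corrected
# value.  This is the order-1 scheme the fractional weights must collapse
# to; coded directly and independently of solve_fde().
classical_pece <- function(rhs, y0, t_end, h) {
  n_steps <- round(t_end / h)
  y <- numeric(n_steps + 1L)
  f <- numeric(n_steps + 1L)
  y[1L] <- y0
  f[1L] <- rhs(0, y0)
  for (n in 0:(n_steps - 1L)) {
    t1 <- (n + 1L) * h
    y_pred <- y0 + h * sum(f[1:(n + 1L)])
    f_pred <- rhs(t1, y_pred)
    w <- c(1, rep(2, n), 1)
    y[n + 2L] <- y0 + h / 2 * sum(c(f[1:(n + 1L)], f_pred) * w)
    f[n + 2L] <- rhs(t1, y[n + 2L])
  }
  list(times = h * (0:n_steps), states = y)
}

# Default fixture profiles in the printed order.
fixture_profiles <- function() {
  list(
    p160_50 = patient_profile(160, 50),
    p140_50 = patient_profile(140, 50),
    p90_60 = patient_profile(90, 60),
    p160_40 = patient_profile(160, 40)
  )
}
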