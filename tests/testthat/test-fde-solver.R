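test_that("problem construction validates its invariants", {
  rhs <- function(t, y) -y
  expect_error(fde_problem(0, rhs, 1, 1, 0.1), "order")
  expect_error(fde_problem(2.1, rhs, 1, 1, 0.1), "order")
  expect_error(fde_problem(0.5, rhs, 1, 1, 0.3), "whole multiple")
  expect_error(fde_problem(0.5, rhs, NaN, 1, 0.1), "finite")
  p <- fde_problem(0.5, rhs, c(1, 2), 1, 0.1)
  expect_s3_class(p, "fde_problem")
  expect_equal(p$n_steps, 10L)
  expect_equal(p$dimension, 2L)
  expect_null(p$initial_slope)
  # second initial condition only for orders above 1; defaults to zero slope
  p2 <- fde_problem(1.5, rhs, 1, 1, 0.1)
  expect_equal(p2$initial_slope, 0)
})

test_that("order-1 solve reduces to the classical exponential and classical PECE", {
  p <- fde_problem(1, function(t, y) -y, 1, t_end = 1, step = 1e-3)
  tr <- solve_fde(p)
  yT <- tr$states[nrow(tr$states), 1]
  expect_equal(yT, exp(-1), tolerance = 1e-5)
  # bitwise-level agreement with an independently coded classical PECE
  cl <- classical_pece(function(t, y) -y, 1, 1, 1e-3)
  expect_lt(max(abs(tr$states[, 1] - cl$states)), 1e-12)
  # the fractional quadrature weights collapse to Euler/trapezoid at order 1
  g <- 1
  n <- 57
  j <- 0:n
  b <- (n + 1 - j)^g - (n - j)^g
  expect_equal(b, rep(1, n + 1), tolerance = 1e-14)
  a0 <- n^(g + 1) - (n - g) * (n + 1)^g
  aj <- (n - 1:n + 2)^(g + 1) + (n - 1:n)^(g + 1) - 2 * (n - 1:n + 1)^(g + 1)
  expect_equal(c(a0, aj) / gamma(g + 2) * gamma(g + 1),
               c(0.5, rep(1, n)), tolerance = 1e-14)
})

test_that("zero right-hand side leaves every order constant", {
  for (g in c(0.3, 0.8, 1, 1.6)) {
    p <- fde_problem(g, function(t, y) 0 * y, c(2.5, -1), 1, 0.05)
    tr <- solve_fde(p)
    expect_true(all(tr$states[, 1] == 2.5))
    expect_true(all(tr$states[, 2] == -1))
  }
})

test_that("solution matches the Mittag-Leffler oracle for linear decay", {
  for (g in c(0.3, 0.5, 0.8, 1.0)) {
    for (lam in c(-1, -0.5)) {
      p <- fde_problem(g, function(t, y) lam * y, 1, t_end = 1, step = 1e-3)
      tr <- solve_fde(p)
      yT <- tr$states[nrow(tr$states), 1]
      expect_equal(yT, mittag_leffler(g, lam), tolerance = 1e-4,
                   label = sprintf("y(1) at gamma=%.1f lambda=%.1f", g, lam))
    }
  }
})

test_that("trajectory structure is a uniform grid starting at the initial state", {
  p <- fde_problem(0.7, function(t, y) -y + t, c(1, 0, 2), 2, 0.01)
  tr <- solve_fde(p)
  expect_equal(tr$states[1, ], c(1, 0, 2))
  expect_equal(tr$times, seq(0, 2, by = 0.01))
  expect_true(all(abs(diff(tr$times) - 0.01) < 1e-12))
  df <- as.data.frame(tr)
  expect_named(df, c("t", "y1", "y2", "y3"))
  expect_equal(nrow(df), 201L)
})

test_that("fractional dynamics carry memory: a restart from the mid-state diverges", {
  g <- 0.6
  p <- fde_problem(g, function(t, y) -y, 1, t_end = 1, step = 1e-3)
  full <- solve_fde(p)
  y_end_full <- full$states[nrow(full$states), 1]
  y_mid <- full$states[501, 1]
  p2 <- fde_problem(g, function(t, y) -y, y_mid, t_end = 0.5, step = 1e-3)
  y_end_restart <- solve_fde(p2)$states[501, 1]
  # difference far above solver tolerance (~1e-6 here): history matters
  expect_gt(abs(y_end_full - y_end_restart), 1e-5 * 10)
  # whereas the classical order-1 flow is memoryless (semigroup property)
  p <- fde_problem(1, function(t, y) -y, 1, t_end = 1, step = 1e-3)
  full1 <- solve_fde(p)
  p2 <- fde_problem(1, function(t, y) -y, full1$states[501, 1],
                    t_end = 0.5, step = 1e-3)
  expect_equal(solve_fde(p2)$states[501, 1],
               full1$states[nrow(full1$states), 1], tolerance = 1e-7)
})

test_that("solver reports the failing step for non-finite right-hand sides", {
  rhs <- function(t, y) if (t > 0.5) NaN else -y
  p <- fde_problem(0.8, rhs, 1, 1, 0.1)
  expect_error(solve_fde(p), "step [0-9]+")
})

test_that("orders above one integrate the initial slope", {
  # D^1.5 y = 0 with y(0) = 1, y'(0) = 2 gives the line 1 + 2t
  p <- fde_problem(1.5, function(t, y) 0 * y, 1, 1, 0.01,
                   initial_slope = 2)
  tr <- solve_fde(p)
  expect_equal(tr$states[, 1], 1 + 2 * tr$times, tolerance = 1e-10)
  # D^1.5 y = -y stays bounded and oscillation-free at this horizon
  p2 <- fde_problem(1.5, function(t, y) -y, 1, 1, 0.01)
  tr2 <- solve_fde(p2)
  expect_true(all(is.finite(tr2$states)))
  expect_equal(tr2$states[nrow(tr2$states), 1],
               mittag_leffler(1.5, -1), tolerance = 1e-3)
})

test_that("empirical convergence order meets the fractional Adams theory", {
  steps <- c(1e-2, 5e-3, 2.5e-3)
  p1 <- fde_problem(1, function(t, y) -y, 1, 1, 1e-2)
  eo1 <- empirical_order(p1, steps, function(t) exp(-t))
  expect_equal(eo1$slope, 2, tolerance = 0.2)
  p05 <- fde_problem(0.5, function(t, y) -y, 1, 1, 1e-2)
  eo05 <- empirical_order(p05, steps,
                          function(t) mittag_leffler(0.5, -t^0.5))
  expect_gte(eo05$slope, 1.3)
  # degenerate fit on an exactly solved problem
  pz <- fde_problem(0.5, function(t, y) 0 * y, 1, 1, 1e-2)
  eoz <- empirical_order(pz, steps, function(t) 1)
  expect_true(eoz$degenerate)
  expect_true(is.na(eoz$slope))
  expect_error(empirical_order(p1, c(1e-2, 5e-3), function(t) exp(-t)),
               "at least 3")
})

test_that("repeated solves are bit-identical", {
  p <- fde_problem(0.65, function(t, y) -y^2 + sin(t), 0.5, 1, 0.01)
  a <- solve_fde(p)
  b <- solve_fde(p)
  expect_identical(a$states, b$states)
})
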