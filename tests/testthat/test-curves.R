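doses8 <- 10^seq(log10(0.0025), log10(8), length.out = 8)

test_that("B-spline fits reproduce constants, interpolate, and contain log-linear curves", {
  # constant curve
  sp <- fit_bspline(doses8, rep(0.5, 8), order = 4, n_basis = 6)
  expect_equal(evaluate_spline(sp, doses8), rep(0.5, 8), tolerance = 1e-8)

  # interpolation regime: n_basis == number of points
  set.seed(3)
  v <- runif(8)
  sp <- fit_bspline(doses8, v, order = 4, n_basis = 8)
  expect_lt(max(abs(evaluate_spline(sp, doses8) - v)), 1e-8)

  # cubic spline space contains linear functions of log10-dose
  v <- 0.9 - 0.2 * log10(doses8)
  sp <- fit_bspline(doses8, v, order = 4, n_basis = 4)
  expect_lt(max(abs(evaluate_spline(sp, doses8) - v)), 1e-6)

  expect_error(fit_bspline(doses8[1:3], c(1, 2, 3), order = 4), "insufficient")
  expect_error(fit_bspline(c(1, 1, 2, 3), c(1, 2, 3, 4)), "increasing")
})

test_that("spline evaluation is linear in the coefficients and guards its span", {
  set.seed(4)
  v1 <- runif(8); v2 <- runif(8)
  s1 <- fit_bspline(doses8, v1, n_basis = 8)
  s2 <- fit_bspline(doses8, v2, n_basis = 8)
  s12 <- s1
  s12$coefficients <- s1$coefficients + s2$coefficients
  expect_equal(evaluate_spline(s12, doses8),
               evaluate_spline(s1, doses8) + evaluate_spline(s2, doses8),
               tolerance = 1e-10)
  s0 <- s1
  s0$coefficients <- s0$coefficients * 0
  expect_equal(evaluate_spline(s0, doses8), rep(0, 8))
  expect_error(evaluate_spline(s1, 100), "span")
  expect_silent(evaluate_spline(s1, 100, extrapolate = TRUE))
})

test_that("normalized AUC handles reference, clamping and shift invariance", {
  expect_equal(curve_auc(doses8, rep(1, 8), reference = 1), 0)
  expect_equal(curve_auc(doses8, rep(0, 8), reference = 1), 1)
  # fully above the reference with clamping on
  expect_equal(curve_auc(doses8, rep(1.2, 8), reference = 1, clamp = TRUE), 0)
  set.seed(5)
  v <- runif(8)
  expect_equal(curve_auc(doses8, v, reference = 1),
               curve_auc(doses8, v + 3, reference = 4), tolerance = 1e-12)
  expect_error(curve_auc(doses8, c(v[-1], NA)), "finite")
})

test_that("IC percentiles: midpoint of a log-linear decline, flat curves, increasing trends", {
  # linear decline from 1 at min dose to 0 at max dose on the log axis:
  # the 50% point sits at the geometric midpoint dose
  v <- seq(1, 0, length.out = 8)
  ics <- ic_from_polynomial(doses8, v, c(25, 50, 75))
  geo_mid <- 10^mean(log10(range(doses8)))
  expect_equal(ics$dose[ics$percentile == 50], geo_mid, tolerance = 1e-6)
  # monotone: IC25 <= IC50 <= IC75 in dose order
  expect_true(all(diff(ics$dose) >= 0))

  flat <- ic_from_polynomial(doses8, rep(0.7, 8))
  expect_true(all(is.na(flat$dose)))

  inc <- ic_from_polynomial(doses8, seq(0, 1, length.out = 8))
  expect_true(all(is.finite(inc$dose)))
  expect_true(all(diff(inc$dose) >= 0))

  expect_error(ic_from_polynomial(doses8[1:3], v[1:3]), "4 dose points")
  expect_error(ic_from_polynomial(doses8, v, percentiles = 0), "0, 100")
})

test_that("four-parameter logistic recovery: EC50, IC50 crossing, Amax asymptote", {
  v <- sigmoid_response(doses8, a0 = 1, amax = 0, ic50 = 0.5, theta = 2)
  s <- curve_summary(doses8, v)
  expect_equal(s$ec50, 0.5, tolerance = 0.01)
  expect_equal(s$ic50, 0.5, tolerance = 0.01)   # y(IC50) = (A0+Amax)/2 = 0.5
  expect_equal(s$amax, 0, tolerance = 0.02)
  expect_gt(s$auc, 0)

  flat <- curve_summary(doses8, rep(1, 8))
  expect_equal(flat$auc, 0)
  expect_true(is.na(flat$ic50))
})

test_that("curve rankings are stable permutations", {
  y <- rbind(1 - 2 * (log10(doses8) - log10(doses8[1])) / 4,
             1 - 1 * (log10(doses8) - log10(doses8[1])) / 4,
             rep(1, 8))
  expect_equal(rank_curves_by_slope(y, doses8), c(1L, 2L, 3L))
  # identical curves: stable input-order tie-break
  same <- matrix(0.5, 4, 8)
  expect_equal(rank_curves_by_slope(same, doses8), 1:4)
  expect_equal(rank_curves_by_dominance(same, doses8), 1:4)
  expect_equal(rank_curves_by_slope(y[1, , drop = FALSE], doses8), 1L)

  # nested curves: topmost ranks first
  nest <- rbind(rep(0.9, 8), rep(0.6, 8), rep(0.3, 8))
  expect_equal(rank_curves_by_dominance(nest, doses8), c(1L, 2L, 3L))
  # exactly half the points higher each way -> tie broken by mean
  a <- c(1, 1, 0, 0, 1, 1, 0, 0); b <- c(0, 0, 2, 2, 0, 0, 2, 2)
  expect_equal(rank_curves_by_dominance(rbind(a, b), doses8), c(2L, 1L))
  # every ranking is a permutation
  set.seed(11)
  r <- matrix(runif(40), 5, 8)
  expect_setequal(rank_curves_by_slope(r, doses8), 1:5)
  expect_setequal(rank_curves_by_dominance(r, doses8), 1:5)
})
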