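test_that("rmse uses the 1/N convention and validates input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(2, 2)), sqrt(0.5))
  expect_error(rmse(1:3, 1:2), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("polynomial fit interpolates noiseless data from a cubic truth", {
  truth <- met_polynomial(c(0.5, -0.03, 0.027))
  co <- noiseless_cohort(truth, v = seq(0.5, 8, length.out = 40))
  fit <- fit_met_polynomial(co, order = 3)
  expect_equal(fit$model$coefficients, truth$coefficients, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-10)
  expect_identical(fit$n, 40L)
})

test_that("order-1 fit on collinear records recovers the exact slope", {
  co <- walk_cohort(velocity = c(1, 2, 3), met = c(1.5, 2.0, 2.5))
  fit <- fit_met_polynomial(co, order = 1)
  expect_equal(fit$model$coefficients, 0.5)
  expect_equal(fit$rmse, 0)
})

test_that("polynomial LS satisfies the normal equations", {
  co <- simulate_cohort(120, copd_reference_model("all"), seed = 5)
  fit <- fit_met_polynomial(co, order = 3)
  X <- outer(co$velocity, 1:3, `^`)
  ortho <- crossprod(X, fit$residuals)
  expect_lt(max(abs(ortho)) / max(abs(crossprod(X, co$met - 1))), 1e-8)
})

test_that("polynomial fit refuses underdetermined or degenerate cohorts", {
  co <- walk_cohort(velocity = c(1, 2, 3), met = c(1.5, 2, 2.5))
  expect_error(fit_met_polynomial(co, order = 3), "distinct velocities")
  same_v <- walk_cohort(velocity = rep(2, 5), met = 1:5)
  expect_error(fit_met_polynomial(same_v, order = 1), "distinct velocities")
})

test_that("fixed-change-point slopes solve the hinge least-squares problem", {
  # data exactly on a single line: all slopes equal, SSE 0
  co <- collinear_cohort(0.5, v = seq(0.5, 8, by = 0.25))
  s <- slopes_given_change_points(co, c(2, 4, 6))
  expect_equal(s$slopes, rep(0.5, 4), tolerance = 1e-10)
  expect_lt(s$sse, 1e-18)
  expect_false(s$rank_deficient)

  # noiseless data from the women's reference model with true change points
  w <- copd_reference_model("women")
  co <- noiseless_cohort(w)
  s <- slopes_given_change_points(co, w$change_points)
  expect_equal(s$slopes, w$slopes, tolerance = 1e-6)
  expect_lt(s$sse, 1e-16)

  # noisy two-segment data: SSE matches explicit normal equations
  set.seed(11)
  v <- runif(40, 0.5, 8)
  met <- predict(met_piecewise(c(0.6, 2.2), 4), v) + rnorm(40, 0, 0.4)
  co <- walk_cohort(velocity = v, met = pmax(met, 0.1))
  s <- slopes_given_change_points(co, 4)
  expect_equal(s$sse, oracle_hinge_sse(co$velocity, co$met, 4),
               tolerance = 1e-10)
})

test_that("an empty segment triggers the rank warning and minimum-norm fallback", {
  co <- walk_cohort(velocity = c(1, 2, 3), met = c(1.5, 2, 2.5))
  expect_warning(s <- slopes_given_change_points(co, c(2.4, 2.6)),
                 "no data points")
  expect_true(s$rank_deficient)
  expect_error(slopes_given_change_points(co, c(2.8, 2.2)), "increasing")
  expect_error(slopes_given_change_points(co, c(0.5, 2)), "inside")
})

test_that("LS/GA fit recovers the generating piecewise model from noiseless data", {
  w <- copd_reference_model("women")
  co <- noiseless_cohort(w)
  fit <- fit_met_piecewise(co, 4, light_ga(bounds = c(1, 7.5)), seed = 3)
  expect_equal(fit$model$change_points, w$change_points, tolerance = 0.05)
  expect_equal(fit$model$slopes, w$slopes, tolerance = 1e-3)
  expect_lt(fit$rmse, 1e-8)
})

test_that("single-segment fit is analytic and matches the order-1 polynomial", {
  co <- collinear_cohort(0.5)
  fit <- fit_met_piecewise(co, 1)
  expect_equal(fit$model$slopes, 0.5)
  expect_equal(fit$rmse, 0)
  noisy <- simulate_cohort(60, met_linear(0.7), noise_sd = 0.3, seed = 9)
  f1 <- fit_met_piecewise(noisy, 1)
  p1 <- fit_met_polynomial(noisy, 1)
  expect_equal(f1$model$slopes, p1$model$coefficients, tolerance = 1e-10)
})

test_that("elitism makes the best SSE non-increasing across generations", {
  co <- simulate_cohort(80, seed = 21)
  fit <- fit_met_piecewise(co, 3, light_ga(), seed = 2)
  for (tr in fit$meta$traces) expect_true(all(diff(tr) <= 1e-12))
})

test_that("richer segmentations never fit worse than the single segment", {
  co <- simulate_cohort(100, seed = 31)
  r1 <- fit_met_piecewise(co, 1)$rmse
  r4 <- fit_met_piecewise(co, 4, light_ga(bounds = c(2.2, 8)), seed = 4)$rmse
  expect_lte(r4, r1 + 1e-9)
})

test_that("the piecewise fit is deterministic given the seed", {
  co <- simulate_cohort(80, seed = 13)
  cfg <- light_ga(bounds = c(2.3, 7.8))
  f1 <- fit_met_piecewise(co, 4, cfg, seed = 99)
  f2 <- fit_met_piecewise(co, 4, cfg, seed = 99)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$rmse, f2$rmse)
})

test_that("infeasible change-point configurations are rejected up front", {
  co <- simulate_cohort(50, seed = 17)
  expect_error(
    fit_met_piecewise(co, 4, ga_config(min_gap = 5, bounds = c(3, 6))),
    "infeasible")
  expect_error(fit_met_piecewise(co, 0), "n_segments")
  expect_error(fit_met_piecewise(co[1:5, ], 4, light_ga()), "at least")
})

test_that("fit reports serialize to JSON with model and metadata", {
  co <- simulate_cohort(60, seed = 23)
  fit <- fit_met_polynomial(co, 3)
  f <- tempfile(fileext = ".json")
  write_fit_report(fit, f)
  doc <- jsonlite::read_json(f)
  expect_equal(doc$model$kind, "polynomial")
  expect_equal(doc$rmse, fit$rmse)
  expect_equal(doc$n, 60L)
})
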