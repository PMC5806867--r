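test_that("LOO on collinear data predicts every held-out record exactly", {
  co <- collinear_cohort(0.5, v = c(1, 2, 3, 4, 5))
  rep <- loo_cv(co, "polynomial", order = 1)
  expect_equal(rep$rmse_cv, 0)
  expect_equal(rep$predictions, co$met)
  expect_identical(rep$n, 5L)
})

test_that("LOO matches an explicit per-fold enumeration on three records", {
  v <- c(1, 2, 3); met <- c(2, 3, 5)
  co <- walk_cohort(velocity = v, met = met)
  # independent oracle: closed-form slope through (0, 1) on each 2-point fold
  expected <- vapply(1:3, function(l) {
    y <- met[-l] - 1; x <- v[-l]
    a <- sum(x * y) / sum(x^2)
    1 + a * v[l]
  }, numeric(1))
  rep <- loo_cv(co, "polynomial", order = 1)
  expect_equal(rep$predictions, expected, tolerance = 1e-12)
  expect_equal(rep$rmse_cv, sqrt(mean((met - expected)^2)))
})

test_that("pearson_r is the product-moment correlation with validity checks", {
  expect_equal(pearson_r(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(pearson_r(c(1, 5, 9), -c(1, 5, 9)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1, 1), "at least 2")
})

test_that("polynomial LOO is invariant to record order", {
  co <- simulate_cohort(40, seed = 3)
  r1 <- loo_cv(co, "polynomial", order = 3)
  perm <- sample(40)
  co2 <- walk_cohort(velocity = co$velocity[perm], met = co$met[perm])
  r2 <- loo_cv(co2, "polynomial", order = 3)
  expect_equal(r1$rmse_cv, r2$rmse_cv, tolerance = 1e-12)
})

test_that("held-out error is no better than in-sample error", {
  co <- simulate_cohort(80, seed = 29)
  fit <- fit_met_polynomial(co, 3)
  rep <- loo_cv(co, "polynomial", order = 3)
  expect_gte(rep$rmse_cv, fit$rmse - 0.02)
  expect_gt(rep$pearson_r, 0.8)
})

test_that("piecewise LOO re-runs the search per fold or reuses change points", {
  co <- simulate_cohort(30, copd_reference_model("women"), noise_sd = 0.4,
                        seed = 41)
  cfg <- ga_config(population_size = 20, generations = 40, restarts = 1,
                   bounds = c(2.6, 7.5))
  fit <- fit_met_piecewise(co, 2, cfg, seed = 1)
  refit <- loo_cv(co, "piecewise", n_segments = 2, config = cfg, seed = 1)
  reuse <- loo_cv(co, "piecewise", n_segments = 2, config = cfg, seed = 1,
                  refit_changepoints = FALSE)
  expect_identical(refit$spec$refit_changepoints, TRUE)
  expect_identical(reuse$spec$refit_changepoints, FALSE)
  for (rep in list(refit, reuse)) {
    expect_length(rep$predictions, 30)
    expect_gte(rep$rmse_cv, fit$rmse - 0.02)
  }
})

test_that("a failing fold aborts with its index", {
  co <- walk_cohort(velocity = c(1, 2, 2, 3), met = c(1.5, 2, 2.1, 2.5))
  # leaving out a record can drop the distinct-velocity count below K + 1
  expect_error(loo_cv(co, "polynomial", order = 3), "fold")
})

test_that("the reference-vs-predicted table pairs records with predictions", {
  co <- simulate_cohort(25, seed = 8)
  rep <- loo_cv(co, "polynomial", order = 3)
  tab <- cv_table(rep, co)
  expect_identical(names(tab), c("velocity", "reference", "predicted"))
  expect_equal(tab$reference, co$met)
  expect_equal(tab$predicted, rep$predictions)
})
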