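women_piecewise <- copd_reference_model("women")
men_piecewise <- copd_reference_model("men")

test_that("linear baseline anchors at 1 MET and matches both printed forms", {
  m <- met_linear()
  expect_equal(predict(m, 0), 1)
  expect_equal(predict(m, 1), 1.5046)
  # historical uptake-scaled form (1.766 v + 3.5) / 3.5 agrees to 4 d.p.
  v <- 3.5
  expect_equal(predict(m, v), (1.766 * v + 3.5) / 3.5, tolerance = 5e-4)
  expect_error(predict(m, -1), "velocity")
})

test_that("polynomial evaluation is 1 + sum a_k v^k", {
  men <- copd_reference_model("men", kind = "polynomial")
  expect_equal(predict(men, 0), 1)
  expect_equal(predict(men, 1), 1 + sum(men$coefficients))
  expect_equal(predict(men, 1), 1.515559)
  expect_equal(round(predict(men, 5), 4), 6.3131)
  # Horner evaluation agrees with the naive power sum on random inputs
  set.seed(1)
  coefs <- rnorm(5)
  m <- met_polynomial(coefs)
  v <- runif(20, 0, 9)
  naive <- 1 + colSums(coefs * t(outer(v, 1:5, `^`)))
  expect_equal(predict(m, v), naive)
  expect_error(met_polynomial(numeric(0)), "non-empty")
})

test_that("intercepts follow the continuity recursion from b1 = 1", {
  expect_equal(derive_intercepts(c(0.3, 0.3, 0.3), c(2, 5)), c(1, 1, 1))
  expect_equal(derive_intercepts(0.7, numeric(0)), 1)
  expect_equal(
    derive_intercepts(c(0.4866, 1.415, 1.99, 4.494), c(2.68, 3.945, 5.798)),
    c(1, -1.488112, -3.756487, -18.274679),
    tolerance = 1e-9)
  expect_error(derive_intercepts(c(1, 2), c(3, 4)), "change points")
  expect_error(derive_intercepts(c(1, 2, 3), c(4, 4)), "increasing")
  expect_error(derive_intercepts(c(1, 2, 3), c(-1, 4)), "positive")
})

test_that("piecewise evaluation selects segments and hits the printed switch points", {
  w <- women_piecewise
  expect_equal(predict(w, 0), 1)
  expect_equal(round(predict(w, 2.68), 3), 2.304)
  expect_equal(round(predict(w, 5.798), 3), 7.782)
  expect_equal(round(switch_points(w), 3), c(2.304, 4.094, 7.782))
  # interior of segment 2 uses slope 1.415 and derived intercept
  expect_equal(predict(w, 3), 1.415 * 3 - 1.488112, tolerance = 1e-9)
  # men's switch points via the explicit segment formula, not the package path
  sp <- switch_points(men_piecewise)
  a <- c(0.4877, 1.544, 2.106, 4.194); V <- c(2.50, 4.429, 5.879)
  b2 <- (a[1] - a[2]) * V[1] + 1
  b3 <- (a[2] - a[3]) * V[2] + b2
  b4 <- (a[3] - a[4]) * V[3] + b3
  expect_equal(sp, c(a[2] * V[1] + b2, a[3] * V[2] + b3, a[4] * V[3] + b4))
  expect_identical(switch_points(met_piecewise(0.5)), numeric(0))
})

test_that("piecewise models are continuous at every change point", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    m <- met_piecewise(runif(n, -2, 5), sort(runif(n - 1, 0.5, 8)))
    eps <- 1e-9
    for (cp in m$change_points)
      expect_lt(abs(predict(m, cp - eps) - predict(m, cp + eps)), 1e-7)
    # re-deriving intercepts reproduces the stored ones exactly
    expect_identical(derive_intercepts(m$slopes, m$change_points),
                     m$intercepts)
    expect_equal(predict(m, 0), 1)
  }
})

test_that("a one-segment piecewise model with the baseline slope equals the baseline", {
  one <- met_piecewise(0.5046)
  v <- seq(0, 10, by = 0.25)
  expect_equal(predict(one, v), predict(met_linear(), v))
})

test_that("the stacked estimate vector splits into slopes then change points", {
  w <- piecewise_from_estimate(c(0.4866, 1.415, 1.99, 4.494,
                                 2.68, 3.945, 5.798))
  expect_equal(w$slopes, women_piecewise$slopes)
  expect_equal(w$change_points, women_piecewise$change_points)
  expect_error(piecewise_from_estimate(1:4), "odd length")
})

test_that("VO2max reference bank reproduces its printed formulas", {
  expect_equal(vo2max_reference("bruce_cubic", 0), 14.76)
  expect_equal(vo2max_reference("bruce_women_a", 0), 3.74)
  expect_equal(vo2max_reference("bruce_cubic", 10),
               14.76 - 1.379 * 10 + 0.451 * 100 - 0.012 * 1000)
  expect_equal(vo2max_reference("bruce_cubic", 10), 34.07)
  expect_equal(vo2max_reference("bruce_men", 8), 2.94 * 8 + 7.65)
  expect_equal(vo2max_reference("bruce_women_b", 5), 4.38 * 5 - 3.9)
  expect_equal(vo2max_reference("bruce_young_men", 5), 3.62 * 5 + 3.91)
  expect_length(vo2max_reference_names(), 5)
  expect_error(vo2max_reference("nope", 5), "unknown")
  expect_error(vo2max_reference("bruce_men", -1), "non-negative")
})

test_that("models round-trip losslessly through JSON", {
  for (m in list(met_linear(0.51), copd_reference_model("men", kind = "polynomial"),
                 women_piecewise, met_piecewise(0.5))) {
    f <- tempfile(fileext = ".json")
    write_met_model(m, f)
    m2 <- read_met_model(f)
    expect_equal(m2, m)
  }
})
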