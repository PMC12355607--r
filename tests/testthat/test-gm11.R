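test_that("a geometric series satisfies the grey equation exactly", {
  x0 <- c(100, 90, 81, 72.9, 65.61)         # ratio q = 0.9
  fit <- fit_gm11(x0)
  # closed form for ratio-q geometric input: a = 2(1-q)/(1+q), u = x0(1)a/(1-q)
  expect_equal(fit$a, 2 / 19, tolerance = 1e-10)
  expect_equal(fit$u, 2000 / 19, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-9)

  acc <- gm11_accuracy(fit)
  expect_equal(acc$c, 0, tolerance = 1e-10)
  expect_equal(acc$p, 1)
  expect_equal(acc$grade, 1L)
  expect_equal(relative_error_band(fit), c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)

  fc <- forecast_gm11(fit, 1)
  expect_equal(fc$forecast, 59.049, tolerance = 1e-9)  # ratio 0.9 continues
  # restored forecast ratio is (1 - a/2)/(1 + a/2)
  fc3 <- forecast_gm11(fit, 3)
  expect_equal(fc3$forecast[2] / fc3$forecast[1], fit$beta, tolerance = 1e-12)
})

test_that("a constant series yields a = 0, u = level, zero residuals", {
  fit <- fit_gm11(rep(7, 5))
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$u, 7, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(forecast_gm11(fit, 2)$forecast, c(7, 7), tolerance = 1e-9)
})

test_that("AGO round-trips and refitting on fitted values is idempotent", {
  set.seed(8)
  x0 <- exp(cumsum(rnorm(8, 0.05, 0.03))) * 50
  expect_equal(diff(c(0, cumsum(x0))), x0)   # AGO then first difference
  fit <- fit_gm11(x0)
  refit <- fit_gm11(fit$fitted)
  expect_equal(refit$a, fit$a, tolerance = 1e-9)
  expect_equal(refit$u, fit$u, tolerance = 1e-9)
})

test_that("parameters are recovered from noise-free generated series", {
  cases <- list(c(a = 0.05, u = 100, x1 = 80, n = 8),
                c(a = -0.0472, u = 98.6, x1 = 110, n = 8),
                c(a = 0.12, u = 15.5, x1 = 12, n = 6))
  for (cs in cases) {
    x0 <- gen_annual_gm_series(cs["a"], cs["u"], cs["x1"], cs["n"])
    fit <- fit_gm11(x0)
    expect_equal(fit$a, unname(cs["a"]), tolerance = 1e-8)
    expect_equal(fit$u, unname(cs["u"]), tolerance = 1e-8)
    expect_equal(gm11_accuracy(fit)$grade, 1L)
    # forecasts continue the generating law
    full <- gen_annual_gm_series(cs["a"], cs["u"], cs["x1"], cs["n"] + 3)
    fc <- forecast_gm11(fit, 3)
    expect_equal(fc$forecast, unname(full[(cs["n"] + 1):(cs["n"] + 3)]),
                 tolerance = 1e-9)
  }
})

test_that("the sign of a sets forecast monotonicity", {
  grow <- fit_gm11(gen_annual_gm_series(-0.06, 50, 40, 8))
  expect_lt(grow$a, 0)
  expect_true(all(diff(forecast_gm11(grow, 5)$forecast) > 0))
  decay <- fit_gm11(gen_annual_gm_series(0.08, 120, 100, 8))
  expect_gt(decay$a, 0)
  expect_true(all(diff(forecast_gm11(decay, 5)$forecast) < 0))
})

test_that("accuracy grading takes the worse of the c and p grades", {
  expect_equal(gm11_grade(0.30, 0.96), 1L)
  expect_equal(gm11_grade(0.40, 0.90), 2L)
  expect_equal(gm11_grade(0.2194, 1), 1L)
  expect_equal(gm11_grade(0.60, 0.99), 3L)   # good p, poor c
  expect_equal(gm11_grade(0.10, 0.75), 3L)   # good c, poor p
  expect_equal(gm11_grade(0.70, 0.50), 4L)
})

test_that("relative error bands summarise per-point fit errors", {
  fake <- structure(list(
    x0 = c(100, 100, 100, 100),
    residuals = c(0, 1, -2, 4)
  ), class = "gm11")
  expect_equal(relative_error_band(fake), c(min = 1, max = 4))
  set.seed(2)
  x0 <- gen_annual_gm_series(0.07, 90, 70, 8) * exp(rnorm(8, 0, 0.02))
  band <- relative_error_band(fit_gm11(x0))
  expect_gte(band[["min"]], 0)
  expect_lte(band[["min"]], band[["max"]])
})

test_that("invalid inputs are rejected", {
  expect_error(fit_gm11(c(1, 2, 3)), "at least 4")
  expect_error(fit_gm11(c(1, -2, 3, 4)), "positive")
  expect_error(fit_gm11(c(1, NA, 3, 4)), "positive")
})

test_that("forecast threshold crossings are reported", {
  fit <- fit_gm11(gen_annual_gm_series(-0.0472, 98.6, 110, 8))
  fc <- forecast_gm11(fit, 3, thresholds = c(O3 = 160))
  expect_equal(unname(fc$exceeds[, "O3"]), fc$forecast > 160)
})
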