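test_that("dust-day screening applies the seasonal ratio thresholds", {
  pm10 <- rep(100, 24); pm25 <- rep(60, 24)
  pm10[12] <- 200; pm25[12] <- 50            # ratio 0.25 at the spike hour
  f <- flag_dust_day(pm10, pm25, as.Date("2022-07-15"))
  expect_true(f$is_dust_affected)
  expect_equal(f$max_hourly_pm10, 200)
  expect_equal(f$min_ratio, 0.25)

  pm25[12] <- 70                             # ratio 0.35: winter-only trigger
  expect_true(flag_dust_day(pm10, pm25, as.Date("2022-01-15"))$is_dust_affected)
  expect_false(flag_dust_day(pm10, pm25, as.Date("2022-07-15"))$is_dust_affected)

  expect_false(flag_dust_day(rep(300, 24), rep(160, 24),
                             as.Date("2022-04-01"))$is_dust_affected)
  na_day <- flag_dust_day(rep(NA_real_, 24), rep(NA_real_, 24),
                          as.Date("2022-04-01"))
  expect_true(is.na(na_day$is_dust_affected))
})

test_that("deduction eligibility needs 2 consecutive hours above 600 or one above 1000", {
  expect_true(deduction_eligible(c(100, 650, 700, 100)))
  expect_true(deduction_eligible(c(100, 1005, 100)))
  expect_false(deduction_eligible(rep(599, 3)))
  expect_false(deduction_eligible(c(650, 100, 700)))   # not consecutive
  expect_false(deduction_eligible(c(650, NA, 700)))    # gap breaks the run
  expect_true(deduction_eligible(c(NA, 601, 602, NA)))
})

test_that("dust contribution matches brute-force recomputation and the printed arithmetic", {
  set.seed(5)
  pm10 <- runif(365, 40, 90)
  dust <- rep(FALSE, 365); dust[sample(365, 22)] <- TRUE
  pm10[dust] <- pm10[dust] + runif(22, 100, 400)
  dc <- dust_contribution(pm10, dust)
  expect_equal(dc$mean_with_dust, mean(pm10))
  expect_equal(dc$mean_deducted, mean(pm10[!dust]))
  expect_equal(dc$increment, mean(pm10) - mean(pm10[!dust]))
  expect_equal(dc$rate, dc$increment / dc$mean_with_dust * 100)
  expect_gte(dc$increment, 0)

  # deducted mean 72 with increment 5 gives the 6.5% contribution rate
  x <- c(rep(72, 343), rep(72 + 5 * 365 / 22, 22))
  f <- c(rep(FALSE, 343), rep(TRUE, 22))
  dc2 <- dust_contribution(x, f)
  expect_equal(dc2$mean_deducted, 72)
  expect_equal(dc2$increment_rounded, 5)
  expect_equal(dc2$rate_rounded, 6.5)

  expect_equal(dust_contribution(pm10, rep(FALSE, 365))$rate, 0)
  expect_error(dust_contribution(pm10, rep(TRUE, 365)), "all days")
})

test_that("index contribution is the share of the with-dust index", {
  ic <- index_contribution(4.45, 4.40, value = 0.05)
  expect_equal(ic$rate_rounded, 1.1)
  expect_equal(index_contribution(4.45, 4.45)$rate, 0)
  ic2 <- index_contribution(5.0, 4.5)
  expect_equal(ic2$value, 0.5)
  expect_equal(ic2$rate, 10.0)
  expect_error(index_contribution(0, 0), "positive")
})

test_that("the dust calendar counts by month and attributes pollution days", {
  days <- as.Date(c("2022-03-10", "2022-04-01", "2022-04-02", "2022-10-20"))
  flags <- data.frame(date = days, is_dust_affected = TRUE,
                      deduction_eligible = FALSE, trigger = "r",
                      max_hourly_pm10 = 300, min_ratio = 0.2)
  aqi <- data.frame(date = days, level = c(3L, 1L, 5L, 2L))
  cal <- dust_day_calendar(flags, aqi)
  expect_equal(unname(cal$monthly_counts[c(3, 4, 10)]), c(1L, 2L, 1L))
  expect_equal(cal$total, 4L)
  expect_equal(cal$caused_pollution_days, 2L)
  expect_equal(cal$no_significant_effect_days, 2L)

  empty <- dust_day_calendar(flags[0, ])
  expect_equal(sum(empty$monthly_counts), 0L)
})
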