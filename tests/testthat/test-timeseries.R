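test_that("daily 24-h means honour the completeness threshold", {
  rec <- make_hourly_day(rep(50, 24))
  d <- aggregate_daily(rec, "station")
  expect_equal(d$PM10, 50)
  expect_equal(d$n_PM10, 24L)

  conc <- rep(50, 24)
  conc[1:5] <- NA  # 19 valid hours, below the 20-hour rule
  d19 <- aggregate_daily(make_hourly_day(conc), "station")
  expect_true(is.na(d19$PM10))
  expect_equal(d19$n_PM10, 19L)
  # the same day passes with a lower configured threshold
  d19b <- aggregate_daily(make_hourly_day(conc), "station", min_valid_hours = 19L)
  expect_equal(d19b$PM10, 50)
})

test_that("city scope is the unweighted mean of station daily values", {
  rec <- rbind(make_hourly_day(rep(60, 24), station = "A"),
               make_hourly_day(rep(80, 24), station = "B"))
  d <- aggregate_daily(rec, "city")
  expect_equal(d$PM10, 70)
  st <- aggregate_daily(rec, "station")
  expect_true(d$PM10 >= min(st$PM10) && d$PM10 <= max(st$PM10))
})

test_that("aggregation is invariant to record order and rejects duplicates", {
  rec <- rbind(make_hourly_day(rnorm(24, 80, 5), station = "A"),
               make_hourly_day(rnorm(24, 60, 5), station = "B"),
               make_hourly_day(rnorm(24, 40, 5), station = "A",
                               pollutant = "PM2.5"))
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(aggregate_daily(rec, "city"), aggregate_daily(shuffled, "city"))
  expect_error(aggregate_daily(rbind(rec, rec[1, ]), "city"), "duplicated")
})

test_that("empty input yields empty output", {
  expect_equal(nrow(aggregate_daily(make_hourly_day(rep(1, 24))[0, ])), 0L)
})

test_that("o3 rolling 8-h max matches window enumeration and validity rules", {
  expect_equal(o3_rolling_8h(rep(100, 24))$o3_8h_max, 100)

  ramp <- as.numeric(1:24)
  oracle <- max(sapply(1:17, function(s) mean(ramp[s:(s + 7)])))
  r <- o3_rolling_8h(ramp)
  expect_equal(r$o3_8h_max, oracle)
  expect_equal(r$o3_8h_max, 20.5)
  expect_equal(r$n_valid_windows, 17L)

  # every window mean is bounded by the single 8-h means it summarises
  x <- runif(24, 0, 200)
  all_means <- sapply(1:17, function(s) mean(x[s:(s + 7)]))
  expect_equal(o3_rolling_8h(x)$o3_8h_max, max(all_means))

  sparse <- rep(NA_real_, 24)
  sparse[17:24] <- 100  # only the last windows retain >= 6 valid hours
  rs <- o3_rolling_8h(sparse)
  expect_lt(rs$n_valid_windows, 14L)
  expect_false(rs$day_valid)
  expect_true(is.na(rs$o3_8h_max))
})

test_that("nearest-rank percentiles are observed values at ceil(p*n)", {
  expect_equal(nearest_rank(1:365, 0.90), 329)
  expect_equal(nearest_rank(1:100, 0.95), 95)
  set.seed(1)
  for (i in 1:20) {
    x <- runif(sample(5:200, 1), 0, 500)
    p <- runif(1, 0.05, 1)
    q <- nearest_rank(x, p)
    expect_true(q %in% x)
    expect_equal(q, sort(x)[ceiling(p * length(x))])
  }
})

test_that("annual statistics use the regulatory conventions", {
  dates <- seq(as.Date("2022-01-01"), as.Date("2022-12-31"), by = "day")
  d <- make_daily(dates, PM10 = rep(72, 365), SO2 = rep(7, 365),
                  NO2 = rep(31, 365), PM25 = rep(42, 365),
                  CO = seq_len(365) / 100, O3 = as.numeric(seq_len(365)))
  s <- annual_stats(d, 2022)
  expect_equal(s$pm10_mean, 72)
  expect_equal(s$o3_8h_p90, 329)              # rank ceil(0.9*365)
  expect_equal(s$co_p95, 3.47)                # rank ceil(0.95*365) = 347
  expect_equal(s$n_valid_days, 365L)
  s95 <- annual_stats(d, 2022, o3_percentile = 0.95)
  expect_equal(s95$o3_8h_p90, ceiling(0.95 * 365))
})

test_that("monthly means average valid days within each calendar month", {
  dates <- as.Date(c("2022-01-03", "2022-01-10", "2022-01-20", "2022-07-01"))
  d <- make_daily(dates, PM10 = c(10, 20, 30, 99))
  mm <- monthly_means(d)
  expect_equal(mm$PM10[1], 20)
  expect_equal(mm$PM10[7], 99)
  expect_true(is.na(mm$PM10[2]))
})
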