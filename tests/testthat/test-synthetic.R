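test_that("the generator is deterministic and non-negative", {
  cfg <- synth_config(seed = 5, n_stations = 1, noise_sd = 0.1)
  a <- gen_hourly_year(cfg)
  b <- gen_hourly_year(cfg)
  expect_identical(a, b)
  expect_true(all(a$records$concentration >= 0))
})

test_that("the noise-free law gives winter-peaking PM and summer-peaking O3", {
  out <- gen_hourly_year(light_config())
  daily <- aggregate_daily(out$records, "city")
  mm <- monthly_means(daily)
  expect_gt(mm$PM10[1], mm$PM10[7])
  expect_gt(mm$PM25[1], mm$PM25[7])
  expect_gt(mm$NO2[1], mm$NO2[7])
  expect_lt(mm$O3[1], mm$O3[7])
  # noise-free monthly means match the configured law for a flat pollutant
  expect_lt(max(abs(mm$PM25 / out$truth$monthly_law_means[, "PM25"] - 1)), 0.2)
})

test_that("the heating multiplier scales SO2 by exactly its factor when noise-free", {
  out <- gen_hourly_year(light_config())   # SO2 amplitude 0, multiplier 2.5
  daily <- aggregate_daily(out$records, "city")
  heat <- heating_label(daily$date)
  ratio <- mean(daily$SO2[heat]) / mean(daily$SO2[!heat])
  expect_equal(ratio, 2.5, tolerance = 1e-10)
})

test_that("injected dust events are recovered exactly by the screening rule", {
  out <- gen_hourly_year(light_config())
  flags <- flag_dust_days(city_hourly(out$records))
  found <- flags$date[!is.na(flags$is_dust_affected) & flags$is_dust_affected]
  expect_setequal(as.character(found), as.character(out$truth$dust_days))
  expect_equal(length(found), 22L)
  cal <- dust_day_calendar(flags)
  expect_equal(unname(cal$monthly_counts[c(3, 4, 5, 7, 8, 9, 10, 11)]),
               c(1L, 6L, 6L, 1L, 1L, 2L, 4L, 1L))
  expect_equal(cal$total, 22L)
})

test_that("with noise the flagged set still contains every injected day", {
  cfg <- synth_config(seed = 13, n_stations = 2, noise_sd = 0.12)
  out <- gen_hourly_year(cfg)
  flags <- flag_dust_days(city_hourly(out$records))
  found <- flags$date[!is.na(flags$is_dust_affected) & flags$is_dust_affected]
  expect_true(all(as.character(out$truth$dust_days) %in% as.character(found)))
})

test_that("a strong injected episode is deduction-eligible", {
  cfg <- light_config()
  cfg$dust <- NULL
  out <- gen_hourly_year(cfg)
  ev <- data.frame(date = as.Date("2022-04-20"), pm10 = 650, ratio = 0.25,
                   duration_h = 2L, start_hour = 10L)
  inj <- inject_dust(out$records, ev)
  flags <- flag_dust_days(city_hourly(inj$records))
  day <- flags[flags$date == ev$date, ]
  expect_true(day$is_dust_affected)
  expect_true(day$deduction_eligible)
})

test_that("zero events means no detections on a sub-threshold baseline", {
  cfg <- light_config()
  cfg$dust <- NULL
  out <- gen_hourly_year(cfg)
  flags <- flag_dust_days(city_hourly(out$records))
  expect_equal(sum(flags$is_dust_affected, na.rm = TRUE), 0L)
})

test_that("overlapping dust events on one day are merged", {
  cfg <- light_config(); cfg$dust <- NULL
  out <- gen_hourly_year(cfg)
  ev <- data.frame(date = as.Date(c("2022-05-01", "2022-05-01")),
                   pm10 = c(300, 500), ratio = 0.25,
                   duration_h = 2L, start_hour = c(9L, 11L))
  expect_message(inj <- inject_dust(out$records, ev), "merged")
  expect_equal(nrow(inj$events), 1L)
  expect_equal(inj$events$pm10, 500)
})

test_that("grey-law annual series carry their ground truth and stay positive", {
  x <- gen_annual_gm_series(0.1, 50, 80, 8)
  expect_equal(unname(attr(x, "truth")), c(0.1, 50))
  expect_true(all(x > 0))
  grow <- gen_annual_gm_series(-0.05, 30, 20, 8)
  expect_true(all(diff(grow) > 0))
  expect_error(gen_annual_gm_series(0.9, 1, 5, 8), "non-positive")

  # 1% noise still yields first-grade fits in the vast majority of draws
  grades <- vapply(1:40, function(s) {
    x <- gen_annual_gm_series(0.05, 100, 80, 8, relative_sd = 0.01, seed = s)
    gm11_accuracy(fit_gm11(x))$grade
  }, integer(1))
  expect_gte(mean(grades == 1L), 0.9)
})

test_that("met series reproduce the configured correlation signs", {
  met <- gen_met_series(default_met_signs(), n_months = 120, strength = 0.9,
                        seed = 4)
  pm <- pearson_matrix(met)
  target <- outer(factorize_signs_for_test(), factorize_signs_for_test())
  off <- upper.tri(target)
  expect_true(all(sign(pm$r[off]) == sign(target[off])))
  # the pattern of the packaged sign table is fully reproduced
  signs <- default_met_signs()
  expect_true(all(sign(pm$r[rownames(signs), colnames(signs)]) == signs))

  weak <- gen_met_series(c(a = 1, b = 1, c = -1), n_months = 400,
                         strength = 0, seed = 4)
  pw <- pearson_matrix(weak)
  expect_lt(mean(abs(pw$r[upper.tri(pw$r)])), 0.1)

  infeasible <- matrix(c(1, 1, 1, -1), 2, 2,
                       dimnames = list(c("m1", "m2"), c("p1", "p2")))
  expect_error(gen_met_series(infeasible), "infeasible")
})
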