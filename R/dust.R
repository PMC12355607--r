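# Dust-day screening and deduction accounting.  A day is dust-affected when
# any hour has city-scope PM10 >= 150 ug/m3 together with a PM2.5/PM10 ratio
# <= 0.30 (<= 0.40 in winter, Dec-Feb).  Monitoring data of dust-affected
# days may be deducted from annual particulate statistics when the episode
# is strong enough (PM10 > 600 for two consecutive hours, or > 1000 for one).

#' Flag one day as dust-affected
#'
#' @param pm10 hourly PM10 (ug/m3), `NA` for missing hours.
#' @param pm25 hourly PM2.5, aligned with `pm10`.
#' @param date the day, used to pick the winter ratio threshold.
#' @param ratio_threshold non-winter PM2.5/PM10 threshold (default 0.30).
#' @param winter_threshold threshold for December-February (default 0.40).
#' @param pm10_trigger hourly PM10 trigger level (default 150 ug/m3).
#' @return list: `date`, `is_dust_affected`, `deduction_eligible`, `trigger`
#'   (text description of the rule that fired), `max_hourly_pm10`,
#'   `min_ratio`, `n_paired_hours`.  When no hour has both channels valid
#'   (with PM10 > 0) the day is not assessable and `is_dust_affected` is `NA`.
#' @export
flag_dust_day <- function(pm10, pm25, date,
                          ratio_threshold = 0.30, winter_threshold = 0.40,
                          pm10_trigger = 150) {
  stopifnot(length(pm10) == length(pm25))
  date <- as.Date(date)
  winter <- as.integer(format(date, "%m")) %in% c(12L, 1L, 2L)
  thr <- if (winter) winter_threshold else ratio_threshold
  paired <- !is.na(pm10) & !is.na(pm25) & pm10 > 0
  out <- list(date = date, is_dust_affected = NA,
              deduction_eligible = deduction_eligible(pm10),
              trigger = NA_character_,
              max_hourly_pm10 = if (any(!is.na(pm10))) max(pm10, na.rm = TRUE) else NA_real_,
              min_ratio = NA_real_,
              n_paired_hours = sum(paired))
  if (!any(paired)) {
    message("flag_dust_day: no paired valid hours on ", format(date))
    return(out)
  }
  ratio <- pm25[paired] / pm10[paired]
  hit <- pm10[paired] >= pm10_trigger & ratio <= thr
  out$is_dust_affected <- any(hit)
  out$min_ratio <- min(ratio)
  if (out$is_dust_affected) {
    out$trigger <- sprintf("hourly PM10 >= %g with PM2.5/PM10 <= %.2f%s",
                           pm10_trigger, thr, if (winter) " (winter)" else "")
  }
  out
}

#' Flag dust-affected days over a period
#'
#' Applies [flag_dust_day()] to every day of a city-scope hourly table.
#'
#' @param hourly city hourly table from [city_hourly()] (needs `date`,
#'   `PM10`, `PM25` columns).
#' @param ... passed to [flag_dust_day()].
#' @return data.frame with one row per day: `date`, `is_dust_affected`,
#'   `deduction_eligible`, `trigger`, `max_hourly_pm10`, `min_ratio`.
#' @export
flag_dust_days <- function(hourly, ...) {
  stopifnot(all(c("date", "PM10", "PM25") %in% names(hourly)))
  parts <- split(hourly, hourly$date)
  rows <- lapply(parts, function(g) {
    f <- flag_dust_day(g$PM10, g$PM25, g$date[1], ...)
    data.frame(date = f$date, is_dust_affected = f$is_dust_affected,
               deduction_eligible = f$deduction_eligible,
               trigger = f$trigger %||% NA_character_,
               max_hourly_pm10 = f$max_hourly_pm10, min_ratio = f$min_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$date), , drop = FALSE]
}

#' Deduction eligibility of a dust episode
#'
#' A day's particulate data may be deducted when hourly PM10 exceeds
#' 600 ug/m3 for at least two consecutive hours, or exceeds 1000 ug/m3 for
#' at least one hour.
#'
#' @param pm10 hourly PM10 series for the day (`NA` allowed).
#' @return logical scalar.
#' @export
deduction_eligible <- function(pm10) {
  x <- pm10
  x[is.na(x)] <- -Inf
  if (any(x > 1000)) return(TRUE)
  r <- rle(x > 600)
  any(r$values & r$lengths >= 2L)
}

#' Dust contribution to the annual PM10 mean
#'
#' The deducted mean excludes dust-affected days from the annual mean of
#' valid daily PM10; the increment is the difference between the full and
#' deducted means and the contribution rate its share of the full mean.
#'
#' @param daily_pm10 data.frame with `date` and `PM10` daily means, or a
#'   numeric vector aligned with `flags`.
#' @param flags data.frame from [flag_dust_days()] (uses `date`,
#'   `is_dust_affected`), or a logical vector.
#' @return list of class `dust_contribution`: `mean_with_dust`,
#'   `mean_deducted`, `increment`, `rate` (raw), plus `increment_rounded`
#'   (integer ug/m3) and `rate_rounded` (one decimal, percent),
#'   `n_days`, `n_dust_days`.
#' @export
dust_contribution <- function(daily_pm10, flags) {
  if (is.data.frame(daily_pm10)) {
    pm10 <- daily_pm10$PM10
    dates <- daily_pm10$date
  } else {
    pm10 <- as.numeric(daily_pm10)
    dates <- seq_along(pm10)
  }
  if (is.data.frame(flags)) {
    i <- match(as.character(dates), as.character(flags$date))
    dust <- flags$is_dust_affected[i]
  } else {
    dust <- as.logical(flags)
  }
  ok <- !is.na(pm10)
  pm10 <- pm10[ok]
  dust <- dust[ok]
  dust[is.na(dust)] <- FALSE
  if (!length(pm10)) stop("no valid daily PM10 values")
  if (all(dust)) stop("all days dust-affected: deducted mean undefined")
  mean_with <- mean(pm10)
  mean_ded <- mean(pm10[!dust])
  inc <- mean_with - mean_ded
  structure(list(
    mean_with_dust = mean_with,
    mean_deducted = mean_ded,
    increment = inc,
    rate = inc / mean_with * 100,
    increment_rounded = round_half_up(inc),
    rate_rounded = round_half_up(inc / mean_with * 100, 1),
    n_days = length(pm10),
    n_dust_days = sum(dust)
  ), class = "dust_contribution")
}

#' @export
print.dust_contribution <- function(x, ...) {
  cat(sprintf(
    "Dust contribution: PM10 mean %.1f -> %.1f ug/m3 (deducted over %d of %d days)\n",
    x$mean_with_dust, x$mean_deducted, x$n_dust_days, x$n_days))
  cat(sprintf("  increment %g ug/m3, contribution rate %.1f%%\n",
              x$increment_rounded, x$rate_rounded))
  invisible(x)
}

#' Dust contribution to the comprehensive index
#'
#' @param composite_with comprehensive index including dust-affected days.
#' @param composite_without comprehensive index after deduction.
#' @param value optional externally supplied contribution value overriding
#'   the difference (reported annual accounts sometimes publish a value
#'   computed under a different deduction convention).
#' @return list with `value` and `rate` (percent of the with-dust index),
#'   plus one-decimal rounded versions.
#' @export
index_contribution <- function(composite_with, composite_without, value = NULL) {
  if (composite_with <= 0) stop("comprehensive index must be positive")
  v <- value %||% (composite_with - composite_without)
  rate <- v / composite_with * 100
  list(value = v, rate = rate,
       value_rounded = round_half_up(v, 2),
       rate_rounded = round_half_up(rate, 1))
}

#' Dust-day calendar and pollution attribution
#'
#' Monthly dust-day counts, the annual total, and (when AQI results are
#' supplied) the split between dust days that caused a pollution day
#' (AQI > 100) and those that did not significantly affect air quality.
#'
#' @param flags data.frame from [flag_dust_days()].
#' @param aqi_results optional AQI table from [daily_aqi()].
#' @return list: `monthly_counts` (length 12), `total`, and with AQI input
#'   `level_counts` over dust days, `caused_pollution_days`,
#'   `no_significant_effect_days`.
#' @export
dust_day_calendar <- function(flags, aqi_results = NULL) {
  dust <- flags[!is.na(flags$is_dust_affected) & flags$is_dust_affected, ]
  mon <- as.integer(format(as.Date(dust$date), "%m"))
  monthly <- vapply(1:12, function(m) sum(mon == m), integer(1))
  names(monthly) <- month.abb
  out <- list(monthly_counts = monthly, total = nrow(dust))
  if (!is.null(aqi_results)) {
    lv <- aqi_results$level[match(as.character(dust$date),
                                  as.character(aqi_results$date))]
    out$level_counts <- vapply(1:6, function(l) sum(lv == l, na.rm = TRUE),
                               integer(1))
    names(out$level_counts) <- LEVEL_LABELS
    out$caused_pollution_days <- sum(lv > 2, na.rm = TRUE)
    out$no_significant_effect_days <- sum(lv <= 2, na.rm = TRUE)
  }
  out
}
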