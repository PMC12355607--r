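# Comprehensive (composite) ambient air quality index: the sum over the six
# criteria pollutants of the annual evaluation statistic divided by its
# Grade-II standard limit, plus year-on-year comparison tables.

#' Comprehensive pollution index
#'
#' Sub-index = annual statistic / Grade-II limit for each of the six
#' criteria pollutants; the comprehensive index is their sum, reported to
#' two decimals.
#'
#' @param stats named numeric vector (or one-row data.frame from
#'   [annual_stats()]) of the six annual statistics, keyed by pollutant:
#'   annual means of SO2, NO2, PM10, PM2.5; 95th percentile of daily CO;
#'   90th percentile of daily O3-8h.
#' @param limits named limits as from [standard_limits()].
#' @return list of class `composite_index`: `sub_indices` (named), `index`
#'   (raw sum) and `index_2dp`.
#' @examples
#' composite_index(c(SO2 = 7, NO2 = 38, PM10 = 74, PM25 = 40, CO = 1.8, O3 = 134))
#' @export
composite_index <- function(stats, limits = standard_limits()) {
  if (is.data.frame(stats)) {
    stats <- c(SO2 = stats$so2_mean, NO2 = stats$no2_mean,
               PM10 = stats$pm10_mean, PM25 = stats$pm25_mean,
               CO = stats$co_p95, O3 = stats$o3_8h_p90)
  }
  names(stats) <- canon_pollutant(names(stats))
  miss <- setdiff(POLLUTANTS, names(stats)[!is.na(stats)])
  if (length(miss)) {
    stop("missing annual statistic for: ",
         paste(POLLUTANT_LABELS[miss], collapse = ", "))
  }
  sub <- stats[POLLUTANTS] / limits[POLLUTANTS]
  structure(list(sub_indices = sub, index = sum(sub),
                 index_2dp = round_half_up(sum(sub), 2)),
            class = "composite_index")
}

#' @export
print.composite_index <- function(x, ...) {
  cat("Comprehensive pollution index:", sprintf("%.2f", x$index_2dp), "\n")
  print(round(x$sub_indices, 3))
  invisible(x)
}

#' Year-on-year change table
#'
#' Signed percent changes per statistic, `(current - previous)/previous *
#' 100`, rounded half-away-from-zero to one decimal.  A zero change is
#' labelled "flat"; a zero previous value yields `NA` with label
#' "undefined".
#'
#' @param current named numeric vector of this year's statistics (may
#'   include the comprehensive index under any extra name).
#' @param previous matching named vector for the comparison year.
#' @return data.frame: `statistic`, `current`, `previous`, `change_pct`
#'   (raw), `change_rounded`, `label` ("up"/"down"/"flat"/"undefined").
#' @examples
#' yoy_change(c(NO2 = 31), c(NO2 = 38)) # -18.4
#' @export
yoy_change <- function(current, previous) {
  keys <- intersect(names(current), names(previous))
  if (!length(keys)) stop("no matching statistics between the two years")
  cur <- as.numeric(current[keys])
  prev <- as.numeric(previous[keys])
  chg <- ifelse(prev == 0, NA_real_, (cur - prev) / prev * 100)
  label <- ifelse(is.na(chg), "undefined",
                  ifelse(chg > 0, "up", ifelse(chg < 0, "down", "flat")))
  data.frame(statistic = keys, current = cur, previous = prev,
             change_pct = chg, change_rounded = round_half_up(chg, 1),
             label = label, stringsAsFactors = FALSE)
}
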