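# Ingestion and aggregation of hourly station records to the regulatory
# daily, monthly and annual statistics.  Days are local civil time,
# [00:00, 24:00) half-open; missing hours are simply absent (no imputation).

#' Read hourly station records from CSV
#'
#' Expected columns: `station_id`, `datetime` (ISO-8601 local, e.g.
#' `2022-01-01T13:00:00` or `2022-01-01 13:00`), `pollutant`, `concentration`
#' and optionally `unit`.  Concentrations are ug/m3 except CO, which is
#' carried in mg/m3 end-to-end; no unit conversion is performed.
#'
#' @param path CSV file path.
#' @return data.frame of hourly records with canonical pollutant codes,
#'   POSIXct timestamps and a `valid` flag (non-missing, non-negative).
#' @export
read_hourly_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "datetime", "pollutant", "concentration")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("hourly CSV missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(gsub("T", " ", raw$datetime), tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d %H"))
  if (anyNA(ts)) stop("unparseable datetime values in ", path)
  hourly_records(
    station_id = as.character(raw$station_id),
    datetime = ts,
    pollutant = raw$pollutant,
    concentration = raw$concentration,
    unit = raw$unit %||% NULL
  )
}

#' Construct a validated hourly record table
#'
#' @param station_id character vector of station identifiers.
#' @param datetime POSIXct timestamps (local civil time; hour-beginning).
#' @param pollutant pollutant codes (`PM2.5` and `PM25` both accepted).
#' @param concentration numeric; `NA` marks a missing/removed hour.
#' @param unit optional character vector of units.
#' @return data.frame with columns station_id, datetime, pollutant,
#'   concentration, unit, valid.
#' @export
hourly_records <- function(station_id, datetime, pollutant, concentration,
                           unit = NULL) {
  pollutant <- canon_pollutant(pollutant)
  concentration <- as.numeric(concentration)
  neg <- !is.na(concentration) & concentration < 0
  if (any(neg)) stop(sum(neg), " hourly record(s) with negative concentration")
  if (is.null(unit)) unit <- ifelse(pollutant == "CO", "mg/m3", "ug/m3")
  df <- data.frame(
    station_id = as.character(station_id),
    datetime = datetime,
    pollutant = pollutant,
    concentration = concentration,
    unit = unit,
    valid = !is.na(concentration),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(df[c("station_id", "datetime", "pollutant")])
  if (any(dup)) {
    ex <- df[dup, , drop = FALSE][1, ]
    stop(sum(dup), " duplicated (station, hour, pollutant) record(s), e.g. ",
         ex$station_id, " ", format(ex$datetime), " ", ex$pollutant)
  }
  df
}

# 24-slot hourly vector (hours 00..23) for one station-day-pollutant.
day_slots <- function(hours, conc) {
  x <- rep(NA_real_, 24L)
  x[hours + 1L] <- conc
  x
}

#' Daily maximum 8-h rolling ozone mean
#'
#' Evaluates the 17 eight-hour windows ending 08:00-24:00 local time (i.e.
#' hours 1-8 through 17-24 of the day).  A window is valid when at least 6
#' of its 8 hours are valid, in which case its mean is taken over the valid
#' hours; the day is valid when at least 14 of the 17 windows are valid.
#'
#' @param x numeric vector of 24 hourly O3 concentrations (ug/m3), `NA` for
#'   missing hours, index 1 = hour beginning 00:00.
#' @return list with `o3_8h_max` (NA when the day is invalid),
#'   `n_valid_windows` and `day_valid`.
#' @export
o3_rolling_8h <- function(x) {
  stopifnot(length(x) == 24L)
  means <- rep(NA_real_, 17L)
  for (s in 1:17) {
    w <- x[s:(s + 7L)]
    if (sum(!is.na(w)) >= 6L) means[s] <- mean(w, na.rm = TRUE)
  }
  nv <- sum(!is.na(means))
  list(
    o3_8h_max = if (nv >= 14L) max(means, na.rm = TRUE) else NA_real_,
    n_valid_windows = nv,
    day_valid = nv >= 14L
  )
}

station_daily <- function(records, min_valid_hours) {
  records$date <- as.Date(records$datetime, tz = "UTC")
  records$hour <- as.integer(format(records$datetime, "%H", tz = "UTC"))
  keys <- interaction(records$station_id, records$date, records$pollutant,
                      drop = TRUE)
  parts <- split(records, keys)
  rows <- lapply(parts, function(g) {
    p <- g$pollutant[1]
    if (p == "O3") {
      slots <- day_slots(g$hour, ifelse(g$valid, g$concentration, NA_real_))
      r8 <- o3_rolling_8h(slots)
      value <- r8$o3_8h_max
      n <- r8$n_valid_windows
    } else {
      ok <- g$valid
      n <- sum(ok)
      value <- if (n >= min_valid_hours) mean(g$concentration[ok]) else NA_real_
    }
    data.frame(station_id = g$station_id[1], date = g$date[1], pollutant = p,
               value = value, n_valid = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

widen_daily <- function(long, scope_col) {
  dates <- sort(unique(long$date))
  scopes <- unique(long[[scope_col]])
  out <- expand.grid(date = dates, scope = scopes, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  for (p in intersect(POLLUTANTS, unique(long$pollutant))) {
    sub <- long[long$pollutant == p, ]
    i <- match(paste(out$date, out$scope),
               paste(sub$date, sub[[scope_col]]))
    out[[p]] <- sub$value[i]
    out[[paste0("n_", p)]] <- ifelse(is.na(i), 0L, sub$n_valid[i])
  }
  out[order(out$scope, out$date), , drop = FALSE]
}

#' Aggregate hourly records to daily summaries
#'
#' Computes per-pollutant 24-h means (daily maximum 8-h mean for O3) for
#' each station, or for the city as the unweighted mean of the stations'
#' valid daily values.  A station day is valid for a pollutant when at
#' least `min_valid_hours` hours are valid (O3 uses the 14-of-17-window
#' rule of [o3_rolling_8h()]).
#'
#' @param records hourly record table as from [hourly_records()].
#' @param scope `"city"` (default) or `"station"`.
#' @param min_valid_hours completeness threshold for 24-h means; default 20.
#' @return data.frame with one row per date (and station when
#'   `scope = "station"`), columns `date`, `scope`, one value column per
#'   pollutant (`NA` when the day is invalid) and `n_<pollutant>` validity
#'   counts (valid hours; valid windows for O3; contributing stations for
#'   city scope).
#' @export
aggregate_daily <- function(records, scope = c("city", "station"),
                            min_valid_hours = 20L) {
  scope <- match.arg(scope)
  if (!nrow(records)) {
    return(data.frame(date = as.Date(character()), scope = character()))
  }
  dup <- duplicated(records[c("station_id", "datetime", "pollutant")])
  if (any(dup)) stop(sum(dup), " duplicated (station, hour, pollutant) record(s)")
  long <- station_daily(records, min_valid_hours)
  if (scope == "station") return(widen_daily(long, "station_id"))
  ok <- !is.na(long$value)
  city <- aggregate(value ~ date + pollutant, data = long[ok, ], FUN = mean)
  nst <- aggregate(value ~ date + pollutant, data = long[ok, ], FUN = length)
  city$n_valid <- nst$value
  city$scope <- "city"
  widen_daily(city, "scope")
}

#' City-scope hourly means
#'
#' Mean over stations of valid hourly values, one row per hour, wide by
#' pollutant.  Used by the dust-day screening rules, which operate on
#' city-scope hourly PM10 and PM2.5.
#'
#' @param records hourly record table.
#' @return data.frame with columns `datetime`, `date`, `hour` and one
#'   column per pollutant present.
#' @export
city_hourly <- function(records) {
  ok <- records$valid
  agg <- aggregate(concentration ~ datetime + pollutant, data = records[ok, ],
                   FUN = mean)
  hours <- sort(unique(agg$datetime))
  out <- data.frame(datetime = hours)
  out$date <- as.Date(out$datetime, tz = "UTC")
  out$hour <- as.integer(format(out$datetime, "%H", tz = "UTC"))
  for (p in intersect(POLLUTANTS, unique(agg$pollutant))) {
    sub <- agg[agg$pollutant == p, ]
    out[[p]] <- sub$concentration[match(out$datetime, sub$datetime)]
  }
  out
}

#' Annual regulatory statistics
#'
#' Annual means of valid daily values for SO2, NO2, PM10 and PM2.5; the
#' 95th nearest-rank percentile of daily CO means; and the 90th (by default)
#' nearest-rank percentile of daily maximum 8-h O3 means.
#'
#' @param daily daily summary table from [aggregate_daily()] (single scope).
#' @param year calendar year to evaluate.
#' @param o3_percentile evaluation percentile for O3-8h; 0.90 by default,
#'   0.95 available by configuration.
#' @return one-row data.frame: `year`, `so2_mean`, `no2_mean`, `pm10_mean`,
#'   `pm25_mean`, `co_p95`, `o3_8h_p90`, `n_valid_days`.
#' @export
annual_stats <- function(daily, year, o3_percentile = 0.90) {
  yr <- as.integer(format(daily$date, "%Y")) == year
  d <- daily[yr, , drop = FALSE]
  if (!nrow(d)) stop("no daily summaries for year ", year)
  stat1 <- function(p, fun) {
    x <- d[[p]]
    x <- x[!is.na(x)]
    if (!length(x)) {
      message("annual_stats: no valid days for ", p, " in ", year)
      return(NA_real_)
    }
    fun(x)
  }
  value_cols <- intersect(POLLUTANTS, names(d))
  data.frame(
    year = year,
    so2_mean = stat1("SO2", mean),
    no2_mean = stat1("NO2", mean),
    pm10_mean = stat1("PM10", mean),
    pm25_mean = stat1("PM25", mean),
    co_p95 = stat1("CO", function(x) nearest_rank(x, 0.95)),
    o3_8h_p90 = stat1("O3", function(x) nearest_rank(x, o3_percentile)),
    n_valid_days = sum(apply(!is.na(d[, value_cols, drop = FALSE]), 1, any))
  )
}

#' Monthly pollutant means
#'
#' Mean of valid daily values per calendar month; empty months yield `NA`.
#'
#' @param daily daily summary table (single scope).
#' @return data.frame with `month` (1-12) and one column per pollutant.
#' @export
monthly_means <- function(daily) {
  mon <- as.integer(format(daily$date, "%m"))
  out <- data.frame(month = 1:12)
  for (p in intersect(POLLUTANTS, names(daily))) {
    out[[p]] <- vapply(1:12, function(m) {
      x <- daily[[p]][mon == m]
      x <- x[!is.na(x)]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1))
  }
  out
}
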