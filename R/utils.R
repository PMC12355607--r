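`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for reported percentages and index values, where
#' halves move away from zero (base [round()] rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(2.5)    # 3
#' round_half_up(-18.45, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Nearest-rank percentile
#'
#' Percentile of a sample by the nearest-rank rule: the value at ascending
#' rank `ceiling(p * n)`.  The result is always an observed value of the
#' series, never an interpolation, matching the convention for annual
#' evaluation statistics (95th percentile of daily CO, 90th percentile of
#' daily maximum 8-h ozone).
#'
#' @param x numeric vector; `NA`s are dropped.
#' @param p percentile in (0, 1].
#' @return a single observed value of `x`, or `NA` if no data.
#' @examples
#' nearest_rank(1:365, 0.90) # 329
#' nearest_rank(1:100, 0.95) # 95
#' @export
nearest_rank <- function(x, p) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p <= 1)
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sort(x)[ceiling(p * length(x))]
}

canon_pollutant <- function(x) {
  up <- toupper(gsub("[._-]", "", x))
  map <- c(
    SO2 = "SO2", NO2 = "NO2", PM10 = "PM10",
    PM25 = "PM25", CO = "CO", O3 = "O3", O38H = "O3"
  )
  out <- unname(map[up])
  if (anyNA(out)) {
    stop("unknown pollutant code(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Meteorological season of a date
#'
#' Spring is March-May, summer June-August, autumn September-November and
#' winter December-February.
#'
#' @param dates a `Date` vector.
#' @return factor with levels spring, summer, autumn, winter.
#' @export
season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
  factor(s, levels = c("spring", "summer", "autumn", "winter"))
}

#' Heating-period label
#'
#' The urban heating period runs from October 10 to April 10 of the next
#' year, both endpoints included; the remainder of the year is the
#' non-heating period.
#'
#' @param dates a `Date` vector.
#' @return logical vector, `TRUE` on heating-period days.
#' @export
heating_label <- function(dates) {
  dates <- as.Date(dates)
  m <- as.integer(format(dates, "%m"))
  d <- as.integer(format(dates, "%d"))
  md <- m * 100L + d
  md >= 1010L | md <= 410L
}

# Independent sub-streams per generator: a fixed odd multiplier folds the
# stream tag into the root seed so adding a generator never perturbs others.
derive_seed <- function(seed, stream) {
  tags <- c(hourly = 11L, station = 23L, dust = 37L, met = 53L,
            annual = 71L, pipeline = 89L)
  if (!stream %in% names(tags)) stop("unknown seed stream: ", stream)
  as.integer((as.double(seed) * 7919 + tags[[stream]] * 104729) %% 2147483629)
}
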