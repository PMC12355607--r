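# IAQI/AQI construction: piecewise-linear interpolation of concentrations
# through regulatory breakpoints, daily AQI as the maximum sub-index, level
# classification and annual compliance tallies.

LEVEL_LABELS <- c("excellent", "good", "mild pollution", "moderate pollution",
                  "heavy pollution", "severe pollution")

#' Individual air quality index (IAQI)
#'
#' Linear interpolation of a concentration within its bracketing breakpoint
#' segment,
#' \deqn{IAQI = (IAQI_{Hi}-IAQI_{Lo})(C-BP_{Lo})/(BP_{Hi}-BP_{Lo}) + IAQI_{Lo},}
#' rounded up to an integer (regulatory convention).  Concentrations above
#' the top of the pollutant's scale are flagged beyond-index and reported
#' as 500.
#'
#' @param pollutant pollutant code (recycled against `conc`).
#' @param conc non-negative concentration in the pollutant's evaluation
#'   units (24-h mean; daily maximum 8-h mean for O3; CO in mg/m3).
#' @param breakpoints breakpoint table, default [aqi_breakpoints()].
#' @return integer IAQI vector with a logical `beyond_index` attribute.
#' @examples
#' iaqi("PM25", 75)   # 100, an exact node
#' iaqi("PM10", 360)  # 215
#' @export
iaqi <- function(pollutant, conc, breakpoints = aqi_breakpoints()) {
  if (any(conc < 0, na.rm = TRUE)) stop("negative concentration in iaqi()")
  n <- max(length(pollutant), length(conc))
  pollutant <- rep_len(canon_pollutant(pollutant), n)
  conc <- rep_len(as.numeric(conc), n)
  out <- rep(NA_integer_, n)
  beyond <- rep(FALSE, n)
  for (p in unique(pollutant)) {
    seg <- breakpoints[breakpoints$pollutant == p, ]
    if (!nrow(seg)) stop("no breakpoints for pollutant ", p)
    seg <- seg[order(seg$conc), ]
    sel <- which(pollutant == p & !is.na(conc))
    for (j in sel) {
      cj <- conc[j]
      if (cj > max(seg$conc)) {
        out[j] <- 500L
        beyond[j] <- TRUE
        next
      }
      hi <- which(seg$conc >= cj)[1]
      if (seg$conc[hi] == cj) {
        out[j] <- as.integer(seg$iaqi[hi])
      } else {
        lo <- hi - 1L
        v <- (seg$iaqi[hi] - seg$iaqi[lo]) / (seg$conc[hi] - seg$conc[lo]) *
          (cj - seg$conc[lo]) + seg$iaqi[lo]
        out[j] <- as.integer(ceiling(v))
      }
    }
  }
  attr(out, "beyond_index") <- beyond
  out
}

#' AQI level classification
#'
#' Six bands: 0-50 excellent, 51-100 good, 101-150 mild, 151-200 moderate,
#' 201-300 heavy, above 300 severe pollution.  Boundary values belong to
#' the lower band.
#'
#' @param aqi numeric AQI values (>= 0).
#' @return integer levels 1-6 with a `labels` attribute.
#' @export
classify_level <- function(aqi) {
  if (any(aqi < 0, na.rm = TRUE)) stop("negative AQI")
  lv <- as.integer(cut(aqi, breaks = c(-Inf, 50, 100, 150, 200, 300, Inf),
                       labels = FALSE))
  attr(lv, "labels") <- LEVEL_LABELS[lv]
  lv
}

#' Daily AQI from daily pollutant statistics
#'
#' For each day, computes the IAQI of every available pollutant statistic,
#' takes the AQI as their maximum, lists the pollutant(s) attaining it as
#' primary when AQI exceeds 50 (all tied pollutants are reported), and
#' classifies the level.
#'
#' @param daily daily summary table from [aggregate_daily()] (single scope),
#'   or any data.frame with a `date` column and pollutant value columns.
#' @param breakpoints breakpoint table, default [aqi_breakpoints()].
#' @return data.frame with `date`, `iaqi_<pollutant>` columns, `aqi`,
#'   `primary` (comma-separated, empty when AQI <= 50), `level` and
#'   `level_label`; days with no valid pollutant are dropped with a message.
#' @export
daily_aqi <- function(daily, breakpoints = aqi_breakpoints()) {
  pols <- intersect(POLLUTANTS, names(daily))
  if (!length(pols)) stop("no pollutant columns in daily summary")
  sub <- lapply(pols, function(p) iaqi(p, daily[[p]], breakpoints))
  names(sub) <- pols
  m <- do.call(cbind, sub)
  valid <- rowSums(!is.na(m)) > 0
  if (!all(valid)) message(sum(!valid), " day(s) with no valid pollutant dropped")
  m <- m[valid, , drop = FALSE]
  aqi <- apply(m, 1, max, na.rm = TRUE)
  primary <- vapply(seq_len(nrow(m)), function(i) {
    if (aqi[i] <= 50) return("")
    paste(POLLUTANT_LABELS[pols[which(m[i, ] == aqi[i])]], collapse = ",")
  }, character(1))
  lv <- classify_level(aqi)
  out <- data.frame(date = daily$date[valid], stringsAsFactors = FALSE)
  for (p in pols) out[[paste0("iaqi_", tolower(p))]] <- m[, p]
  out$aqi <- as.integer(aqi)
  out$primary <- primary
  out$level <- lv
  out$level_label <- LEVEL_LABELS[lv]
  out
}

#' Annual AQI tallies
#'
#' Day counts and shares per level, the compliance rate (share of level 1-2
#' days), per-season compliance, and per-pollutant primary-pollutant day
#' counts.
#'
#' @param results AQI result table from [daily_aqi()].
#' @return list with `n_days`, `level_counts`, `level_rates` (percent,
#'   1 decimal), `compliance_rate`, `pollution_days`, `season_compliance`
#'   and `primary_days`.
#' @export
annual_aqi_summary <- function(results) {
  n <- nrow(results)
  if (!n) stop("no valid AQI days to summarise")
  counts <- vapply(1:6, function(l) sum(results$level == l), integer(1))
  names(counts) <- LEVEL_LABELS
  rates <- round_half_up(counts / n * 100, 1)
  compliance <- round_half_up(sum(counts[1:2]) / n * 100, 1)
  season <- season_of(results$date)
  season_comp <- vapply(levels(season), function(s) {
    i <- season == s
    if (!any(i)) return(NA_real_)
    round_half_up(mean(results$level[i] <= 2) * 100, 1)
  }, numeric(1))
  prim <- unlist(strsplit(results$primary[results$primary != ""], ","))
  primary_days <- sort(table(prim), decreasing = TRUE)
  list(
    n_days = n,
    level_counts = counts,
    level_rates = rates,
    compliance_rate = compliance,
    pollution_days = sum(counts[3:6]),
    season_compliance = season_comp,
    primary_days = primary_days
  )
}
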