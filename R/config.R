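# Packaged regulatory tables.  Shipped as versioned plain-text config under
# inst/extdata so that a different jurisdiction's tables can be swapped in
# without touching code.

config_file <- function(name) {
  path <- system.file("extdata", name, package = "oasisaq")
  if (!nzchar(path)) stop("packaged config file not found: ", name)
  path
}

#' IAQI breakpoint table
#'
#' The piecewise-linear breakpoints mapping pollutant concentrations to
#' individual air quality index (IAQI) nodes \{0, 50, 100, 150, 200, 300,
#' 400, 500\}.  The packaged default is the table of the Chinese AQI
#' technical regulation (24-h means for SO2, NO2, PM10, PM2.5, CO; daily
#' maximum 8-h mean for O3, whose scale tops out at IAQI 300).
#'
#' @param path optional path to an alternative CSV with columns
#'   `pollutant, period, iaqi, conc`.
#' @return data.frame of breakpoints, validated for strictly increasing,
#'   contiguous segments per pollutant.
#' @export
aqi_breakpoints <- function(path = NULL) {
  bp <- read.csv(path %||% config_file("aqi_breakpoints.csv"),
                 stringsAsFactors = FALSE)
  need <- c("pollutant", "period", "iaqi", "conc")
  if (!all(need %in% names(bp))) {
    stop("breakpoint table must have columns: ", paste(need, collapse = ", "))
  }
  bp$pollutant <- canon_pollutant(bp$pollutant)
  for (p in unique(bp$pollutant)) {
    seg <- bp[bp$pollutant == p, ]
    seg <- seg[order(seg$iaqi), ]
    if (any(diff(seg$conc) <= 0) || any(diff(seg$iaqi) <= 0)) {
      stop("breakpoints for ", p, " must be strictly increasing")
    }
  }
  bp
}

#' Grade-II annual evaluation limits
#'
#' Standard limits used as denominators of the comprehensive pollution
#' index: annual means for SO2 (60), NO2 (40), PM10 (70) and PM2.5
#' (35 ug/m3); the 95th percentile of daily means for CO (4 mg/m3); and the
#' 90th percentile of daily maximum 8-h means for O3 (160 ug/m3).
#'
#' @param path optional path to an alternative CSV with columns
#'   `pollutant, limit, statistic, unit`.
#' @return named numeric vector of limits keyed by canonical pollutant.
#' @export
standard_limits <- function(path = NULL) {
  lim <- read.csv(path %||% config_file("standard_limits.csv"),
                  stringsAsFactors = FALSE)
  out <- stats::setNames(lim$limit, canon_pollutant(lim$pollutant))
  if (any(out <= 0)) stop("standard limits must be positive")
  out
}

#' Spearman critical values
#'
#' Two-tailed critical values W_P of the Spearman rank correlation
#' coefficient for series lengths n = 5..20 at alpha = 0.05 and 0.01.
#' A trend is significant when |rs| >= W_P.
#'
#' @param path optional path to an alternative CSV with columns
#'   `n, alpha_05, alpha_01`.
#' @return data.frame of critical values.
#' @export
spearman_critical <- function(path = NULL) {
  read.csv(path %||% config_file("spearman_critical.csv"),
           stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' Reads the packaged YAML configuration driving [run_analysis()] in
#' synthetic mode: generator baselines and amplitudes, dust-event schedule,
#' AQI options, grey-analysis parameters and GM(1,1) series definitions.
#'
#' @param path optional path to an alternative YAML file.
#' @return nested list.
#' @export
default_config <- function(path = NULL) {
  yaml::read_yaml(path %||% config_file("default_config.yaml"))
}
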