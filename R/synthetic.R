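# Seeded synthetic station data with the statistical structure the analysis
# assumes: winter-peaking ("U-shaped") PM10/PM2.5/NO2/CO and summer-peaking
# ("inverted U-shaped") O3 monthly cycles, a heating-period multiplier for
# SO2, rectangular dust spikes with a low PM2.5/PM10 ratio, meteorology with
# configurable correlation signs, and annual series following a known
# GM(1,1) law.  Every generator is deterministic for a fixed seed and
# returns the ground truth alongside the data.

#' Synthetic-data configuration
#'
#' Defaults describe a mid-sized arid-region city: annual daily-scale
#' baselines near the observed levels (PM10 65, PM2.5 40, NO2 30, SO2 7,
#' O3 70 ug/m3; CO 0.9 mg/m3), log-scale seasonal amplitudes giving
#' winter/summer contrasts of roughly 2-3x, lognormal multiplicative hourly
#' noise, a 2.5x heating-period multiplier on SO2 (October 10 - April 10),
#' and 22 dust events distributed over March-November as
#' (1, 6, 6, 1, 1, 2, 4, 1) events in months (3, 4, 5, 7, 8, 9, 10, 11).
#'
#' @param seed root seed; independent sub-streams are derived per generator.
#' @param year calendar year to simulate.
#' @param n_stations number of monitoring stations.
#' @param noise_sd SD of the hourly log-scale noise (0 = deterministic law).
#' @param station_spread SD of log-scale station offsets.
#' @param heating_multiplier factor applied to SO2 during the heating period.
#' @param baselines,amplitudes named per-pollutant level and log-scale
#'   seasonal amplitude.
#' @param dust list: `counts` (named by month number), `pm10_range`,
#'   `ratio` (PM2.5/PM10 during events, in (0,1)), `duration_h`.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, year = 2022L, n_stations = 2L,
                         noise_sd = 0.12, station_spread = 0.05,
                         heating_multiplier = 2.5,
                         baselines = c(SO2 = 7, NO2 = 30, PM10 = 65,
                                       PM25 = 40, CO = 0.9, O3 = 70),
                         amplitudes = c(SO2 = 0, NO2 = 0.35, PM10 = 0.40,
                                        PM25 = 0.50, CO = 0.50, O3 = 0.60),
                         dust = list(counts = c("3" = 1, "4" = 6, "5" = 6,
                                                "7" = 1, "8" = 1, "9" = 2,
                                                "10" = 4, "11" = 1),
                                     pm10_range = c(200, 700),
                                     ratio = 0.25, duration_h = 3L)) {
  stopifnot(all(baselines > 0), noise_sd >= 0, n_stations >= 1)
  names(baselines) <- canon_pollutant(names(baselines))
  names(amplitudes) <- canon_pollutant(names(amplitudes))
  if (!all(names(baselines) %in% names(amplitudes))) {
    stop("every baseline pollutant needs a seasonal amplitude")
  }
  if (!is.null(dust)) stopifnot(dust$ratio > 0, dust$ratio < 1)
  structure(list(seed = as.integer(seed), year = as.integer(year),
                 n_stations = as.integer(n_stations), noise_sd = noise_sd,
                 station_spread = station_spread,
                 heating_multiplier = heating_multiplier,
                 baselines = baselines, amplitudes = amplitudes,
                 dust = dust), class = "synth_config")
}

# Deterministic hourly law: log-scale sinusoid peaking on Jan 1 for
# combustion/particulate pollutants and July 2 (doy 183) for O3, a mild
# afternoon diurnal cycle for O3, and the heating multiplier on SO2.
synth_law <- function(config, pollutant, doy, hour, heating) {
  peak <- if (pollutant == "O3") 183 else 1
  base <- config$baselines[[pollutant]] *
    exp(config$amplitudes[[pollutant]] * cos(2 * pi * (doy - peak) / 365))
  if (pollutant == "O3") base <- base * exp(0.3 * cos(2 * pi * (hour - 15) / 24))
  if (pollutant == "SO2") base <- base * ifelse(heating, config$heating_multiplier, 1)
  base
}

#' Generate one year of synthetic hourly station records
#'
#' @param config a [synth_config()].
#' @return list with `records` (hourly record table as accepted by
#'   [aggregate_daily()]) and `truth`: injected dust events and days,
#'   noise-free expected monthly means per pollutant, and the configuration.
#' @export
gen_hourly_year <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  hours <- seq(as.POSIXct(paste0(config$year, "-01-01 00:00:00"), tz = "UTC"),
               as.POSIXct(paste0(config$year, "-12-31 23:00:00"), tz = "UTC"),
               by = "hour")
  nh <- length(hours)
  dates <- as.Date(hours, tz = "UTC")
  doy <- as.integer(format(hours, "%j", tz = "UTC"))
  hr <- as.integer(format(hours, "%H", tz = "UTC"))
  heating <- heating_label(dates)

  set.seed(derive_seed(config$seed, "station"))
  st_fac <- exp(rnorm(config$n_stations, 0, config$station_spread))
  st_ids <- sprintf("ST%02d", seq_len(config$n_stations))

  pols <- canon_pollutant(names(config$baselines))
  set.seed(derive_seed(config$seed, "hourly"))
  recs <- vector("list", length(pols) * config$n_stations)
  i <- 0L
  monthly_law <- matrix(NA_real_, 12, length(pols),
                        dimnames = list(month.abb, pols))
  mon <- as.integer(format(hours, "%m", tz = "UTC"))
  for (p in pols) {
    law <- synth_law(config, p, doy, hr, heating)
    monthly_law[, p] <- vapply(1:12, function(m) mean(law[mon == m]), numeric(1))
    for (s in seq_len(config$n_stations)) {
      noise <- if (config$noise_sd > 0) exp(rnorm(nh, 0, config$noise_sd)) else 1
      i <- i + 1L
      recs[[i]] <- data.frame(
        station_id = st_ids[s], datetime = hours, pollutant = p,
        concentration = law * st_fac[s] * noise,
        unit = if (p == "CO") "mg/m3" else "ug/m3",
        valid = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))

  truth <- list(config = config, monthly_law_means = monthly_law,
                dust_events = NULL, dust_days = as.Date(character()))
  if (!is.null(config$dust) && all(c("PM10", "PM25") %in% pols)) {
    events <- sample_dust_events(config)
    inj <- inject_dust(records, events)
    records <- inj$records
    truth$dust_events <- inj$events
    truth$dust_days <- sort(unique(inj$events$date))
  }
  list(records = records, truth = truth)
}

# Draw the dust-event schedule from the config counts (one entry per event).
sample_dust_events <- function(config) {
  set.seed(derive_seed(config$seed, "dust"))
  d <- config$dust
  ev <- list()
  for (m in names(d$counts)) {
    mo <- as.integer(m)
    k <- d$counts[[m]]
    first <- as.Date(sprintf("%d-%02d-01", config$year, mo))
    ndays <- as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1,
                               "%d"))
    days <- sample(ndays, k)
    for (dd in days) {
      ev[[length(ev) + 1L]] <- data.frame(
        date = as.Date(sprintf("%d-%02d-%02d", config$year, mo, dd)),
        pm10 = runif(1, d$pm10_range[1], d$pm10_range[2]),
        ratio = d$ratio,
        duration_h = d$duration_h,
        start_hour = sample(8:18, 1)
      )
    }
  }
  do.call(rbind, ev)
}

#' Inject dust spikes into hourly records
#'
#' On each event day, raises hourly PM10 at all stations to the event
#' magnitude for `duration_h` hours from `start_hour`, holding PM2.5 at
#' `ratio * pm10` so the screening ratio is unambiguous.  Spikes are
#' rectangular in time.  Overlapping events on one day are merged by taking
#' the maximum magnitude over the union of their hours.
#'
#' @param records hourly record table.
#' @param events data.frame with columns `date`, `pm10`, `ratio`,
#'   `duration_h`, `start_hour`.
#' @return list with modified `records` and the `events` actually applied
#'   (one row per event day after merging).
#' @export
inject_dust <- function(records, events) {
  stopifnot(all(c("date", "pm10", "ratio", "duration_h", "start_hour")
                %in% names(events)))
  if (anyDuplicated(events$date)) {
    message("inject_dust: overlapping events on one day merged")
    events <- do.call(rbind, lapply(split(events, events$date), function(g) {
      g[which.max(g$pm10), , drop = FALSE]
    }))
  }
  rec_date <- as.Date(records$datetime, tz = "UTC")
  rec_hour <- as.integer(format(records$datetime, "%H", tz = "UTC"))
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    hrs <- e$start_hour + seq_len(e$duration_h) - 1L
    hit <- rec_date == e$date & rec_hour %in% hrs
    pm10 <- hit & records$pollutant == "PM10"
    pm25 <- hit & records$pollutant == "PM25"
    records$concentration[pm10] <- e$pm10
    records$concentration[pm25] <- e$pm10 * e$ratio
  }
  list(records = records, events = events[order(events$date), ])
}

#' Generate an annual series following a GM(1,1) law
#'
#' Values follow the restored-value law of the grey difference equation with
#' development coefficient `a` and grey action `u`, starting at `x1`,
#' optionally perturbed by Gaussian noise with SD `relative_sd * value`.
#'
#' @param a development coefficient (negative = growing series).
#' @param u grey action quantity.
#' @param x1 first value of the series.
#' @param n series length (>= 4).
#' @param relative_sd relative noise level; 0 gives the exact law.
#' @param seed optional seed for the noise stream.
#' @return numeric series of length `n` with attribute `truth = c(a, u)`.
#' @export
gen_annual_gm_series <- function(a, u, x1, n, relative_sd = 0, seed = NULL) {
  stopifnot(n >= 4, x1 > 0)
  x0 <- gm11_restored(x1, a, u, n)
  if (any(x0 <= 0)) stop("grey parameters yield a non-positive series")
  if (relative_sd > 0) {
    if (!is.null(seed)) set.seed(derive_seed(seed, "annual"))
    x0 <- x0 + rnorm(n, 0, relative_sd * x0)
    if (any(x0 <= 0)) stop("noise drove the series non-positive; lower relative_sd")
  }
  structure(x0, truth = c(a = a, u = u))
}

#' Table of meteorology/pollutant correlation signs
#'
#' The qualitative pattern typical of an arid northern city with coal-fired
#' winter heating: precipitation, wind speed, temperature and vapor pressure
#' anti-correlated with the combustion/particulate pollutants and positively
#' correlated with O3; mean pressure and relative humidity the reverse.
#'
#' @return sign matrix (meteorological variables x pollutants) with entries
#'   in \{-1, +1\}.
#' @export
default_met_signs <- function() {
  met <- c(precipitation = -1, pressure = 1, wind_speed = -1,
           temperature = -1, vapor_pressure = -1, humidity = 1)
  pol <- c(PM25 = 1, PM10 = 1, NO2 = 1, SO2 = 1, CO = 1, O3 = -1)
  outer(met, pol)
}

# One-factor decomposition of a pairwise sign matrix: mat[i, j] must equal
# row_sign[i] * col_sign[j].  Anything else cannot be realised by a single
# latent factor and is rejected as infeasible.
factorize_signs <- function(mat) {
  if (!all(mat %in% c(-1, 0, 1))) stop("sign matrix entries must be -1, 0 or +1")
  anchor <- which(rowSums(mat != 0) > 0)[1]
  if (is.na(anchor)) stop("sign matrix has no non-zero entries")
  col_s <- mat[anchor, ]
  row_s <- vapply(seq_len(nrow(mat)), function(i) {
    j <- which(mat[i, ] != 0 & col_s != 0)[1]
    if (is.na(j)) 0 else mat[i, j] / col_s[j]
  }, numeric(1))
  names(row_s) <- rownames(mat)
  check <- outer(row_s, col_s)
  if (any(check != mat)) {
    stop("infeasible sign matrix: not representable by a one-factor structure")
  }
  c(row_s, col_s)
}

#' Generate monthly meteorology/pollutant series with target correlation signs
#'
#' Gaussian one-factor construction: every variable v is
#' `sign_v * sqrt(strength) * F + sqrt(1 - strength) * eps_v` on a latent
#' monthly factor F, so each pair (u, v) has correlation
#' `sign_u * sign_v * strength` in expectation and the empirical correlation
#' signs match the configured pattern.
#'
#' @param signs either a named sign vector per variable (values -1, 0, +1)
#'   or a pairwise sign matrix such as [default_met_signs()], which is
#'   factorized (an unfactorizable matrix is rejected as infeasible).
#' @param n_months number of monthly observations.
#' @param strength common squared loading in (0, 1); default 0.8.
#' @param seed seed for the stream.
#' @return data.frame of `n_months` rows, one column per variable, plus an
#'   attribute `target_r` with the implied correlation matrix.
#' @export
gen_met_series <- function(signs = default_met_signs(), n_months = 120,
                           strength = 0.8, seed = 1L) {
  stopifnot(strength >= 0, strength < 1, n_months >= 3)
  if (is.matrix(signs)) signs <- factorize_signs(signs)
  if (is.null(names(signs)) || any(!nzchar(names(signs)))) {
    stop("signs must be named")
  }
  set.seed(derive_seed(seed, "met"))
  f <- rnorm(n_months)
  lam <- signs * sqrt(strength)
  out <- as.data.frame(vapply(seq_along(signs), function(v) {
    lam[v] * f + sqrt(1 - lam[v]^2) * rnorm(n_months)
  }, numeric(n_months)))
  names(out) <- names(signs)
  attr(out, "target_r") <- outer(lam, lam) + diag(1 - lam^2)
  out
}
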