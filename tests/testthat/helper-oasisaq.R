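# Shared fixtures and independent oracles used across the suite.

# One station-day of hourly records for a single pollutant.
make_hourly_day <- function(conc, date = as.Date("2022-06-15"),
                            station = "ST01", pollutant = "PM10") {
  stopifnot(length(conc) == 24L)
  hourly_records(
    station_id = station,
    datetime = as.POSIXct(paste(date, sprintf("%02d:00:00", 0:23)), tz = "UTC"),
    pollutant = pollutant,
    concentration = conc
  )
}

# Wide daily summary table from named pollutant vectors.
make_daily <- function(dates, ...) {
  vals <- list(...)
  df <- data.frame(date = as.Date(dates), scope = "city",
                   stringsAsFactors = FALSE)
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  df
}

# All permutations of 1..n (small n), one per row.
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}

# Brute-force grey relational degrees with explicit elementwise loops,
# independent of the vectorized implementation.
gra_brute <- function(ref, comps, xi) {
  n <- length(ref)
  refn <- sapply(seq_len(n), function(k) ref[k] / ref[1])
  m_seqs <- lapply(comps, function(x) sapply(seq_len(n), function(k) x[k] / x[1]))
  deltas <- lapply(m_seqs, function(s) abs(refn - s))
  M <- max(unlist(deltas)); m <- min(unlist(deltas))
  sapply(deltas, function(d) {
    co <- numeric(n)
    for (k in seq_len(n)) co[k] <- (m + xi * M) / (d[k] + xi * M)
    mean(co)
  })
}

# Piecewise-linear IAQI oracle via stats::approx on the breakpoint nodes.
iaqi_oracle <- function(pollutant, conc, bp = aqi_breakpoints()) {
  seg <- bp[bp$pollutant == pollutant, ]
  ceiling(stats::approx(seg$conc, seg$iaqi, xout = conc)$y)
}

# Per-variable polarity implied by the packaged sign table.
factorize_signs_for_test <- function() {
  oasisaq:::factorize_signs(default_met_signs())
}

# Small, fast synthetic configuration used by generator/pipeline tests.
light_config <- function(noise_sd = 0) {
  synth_config(seed = 42L, year = 2022L, n_stations = 1L,
               noise_sd = noise_sd, station_spread = 0)
}
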