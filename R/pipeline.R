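# One-command orchestration of the full analysis chain on synthetic (or
# user-supplied) data, and serialization of the resulting report bundle.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    message("stage '", name, "' failed: ", conditionMessage(e))
    list(error = conditionMessage(e))
  })
}

stage_failed <- function(x) is.list(x) && !is.data.frame(x) && !is.null(x$error)

stats_vector <- function(stats_row) {
  c(SO2 = stats_row$so2_mean, NO2 = stats_row$no2_mean,
    PM10 = stats_row$pm10_mean, PM25 = stats_row$pm25_mean,
    CO = stats_row$co_p95, O3 = stats_row$o3_8h_p90)
}

#' Run the full air-quality analysis pipeline
#'
#' Executes every stage on one configuration: synthetic data generation,
#' daily/monthly/annual aggregation, AQI tallies, dust screening and
#' contribution accounting, annual indicator series with comprehensive
#' index and year-on-year comparison, Spearman trend decisions,
#' meteorology/pollutant correlation matrices, grey relational analysis,
#' and GM(1,1) fits with accuracy grades and forecasts.  A failure in one
#' stage is recorded in its section and does not abort the others.
#'
#' @param config a configuration list as from [default_config()], or a path
#'   to a YAML file of the same shape.
#' @param seed optional root seed overriding the configured one.
#' @param hourly optional hourly record table; when supplied it replaces the
#'   synthetic generator's records (the generator's ground truth is then
#'   unavailable).
#' @return list of class `report_bundle` with sections `provenance`,
#'   `aqi`, `dust`, `comparison`, `trend`, `correlations`, `gra`, `gm11`.
#' @export
run_analysis <- function(config = default_config(), seed = NULL,
                         hourly = NULL) {
  if (is.character(config)) config <- default_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  year <- config$year %||% 2022L

  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  config_md5 <- unname(tools::md5sum(tf))
  unlink(tf)

  bundle <- list(provenance = list(
    package = "oasisaq",
    version = as.character(utils::packageVersion("oasisaq")),
    seed = seed, year = year, config_md5 = config_md5
  ))

  gen <- config$generator %||% list()
  truth <- NULL
  if (is.null(hourly)) {
    synth <- run_stage("synthetic", {
      cfg <- synth_config(
        seed = seed, year = year,
        n_stations = config$n_stations %||% 2L,
        noise_sd = gen$noise_sd %||% 0.12,
        heating_multiplier = gen$heating_multiplier %||% 2.5,
        baselines = unlist(gen$baselines %||%
                             list(SO2 = 7, NO2 = 30, PM10 = 65, PM25 = 40,
                                  CO = 0.9, O3 = 70)),
        amplitudes = unlist(gen$amplitudes %||%
                              list(SO2 = 0, NO2 = 0.35, PM10 = 0.40,
                                   PM25 = 0.50, CO = 0.50, O3 = 0.60)),
        dust = if (is.null(gen$dust)) NULL else
          list(counts = unlist(gen$dust$counts),
               pm10_range = unlist(gen$dust$pm10_range),
               ratio = gen$dust$ratio, duration_h = gen$dust$duration_h)
      )
      gen_hourly_year(cfg)
    })
    if (stage_failed(synth)) {
      bundle$synthetic <- synth
      class(bundle) <- "report_bundle"
      return(bundle)
    }
    hourly <- synth$records
    truth <- synth$truth
  }

  min_hours <- config$aqi$min_valid_hours %||% 20L
  o3_pct <- config$aqi$o3_percentile %||% 0.90
  daily <- run_stage("daily", aggregate_daily(hourly, "city", min_hours))

  bundle$aqi <- run_stage("aqi", {
    res <- daily_aqi(daily)
    list(results = res, summary = annual_aqi_summary(res),
         monthly_means = monthly_means(daily),
         annual_stats = annual_stats(daily, year, o3_pct))
  })

  bundle$dust <- run_stage("dust", {
    ch <- city_hourly(hourly)
    flags <- flag_dust_days(ch)
    contrib <- dust_contribution(daily[, c("date", "PM10")], flags)
    cal <- dust_day_calendar(flags, if (!stage_failed(bundle$aqi))
      bundle$aqi$results else NULL)
    idx <- NULL
    if (!stage_failed(bundle$aqi) && !anyNA(stats_vector(bundle$aqi$annual_stats))) {
      with_stats <- stats_vector(bundle$aqi$annual_stats)
      dusty <- flags$date[!is.na(flags$is_dust_affected) & flags$is_dust_affected]
      ded <- daily[!daily$date %in% dusty, , drop = FALSE]
      ded_stats <- with_stats
      ded_stats["PM10"] <- mean(ded$PM10, na.rm = TRUE)
      ded_stats["PM25"] <- mean(ded$PM25, na.rm = TRUE)
      idx <- index_contribution(composite_index(with_stats)$index,
                                composite_index(ded_stats)$index)
    }
    list(flags = flags, contribution = contrib, calendar = cal,
         index_contribution = idx,
         truth_dust_days = if (!is.null(truth)) truth$dust_days else NULL)
  })

  gm_cfg <- config$gm11 %||% list()
  annual_series <- run_stage("annual_series", {
    if (is.null(gm_cfg$series)) stop("no annual indicator series configured")
    yrs <- unlist(gm_cfg$years)
    m <- vapply(names(gm_cfg$series), function(nm) {
      s <- gm_cfg$series[[nm]]
      gen_annual_gm_series(s$a, s$u, s$x1, length(yrs),
                           gm_cfg$noise_sd %||% 0, seed + match(nm, names(gm_cfg$series)))
    }, numeric(length(unlist(gm_cfg$years))))
    rownames(m) <- yrs
    m
  })

  if (!stage_failed(annual_series)) {
    bundle$comparison <- run_stage("comparison", {
      n <- nrow(annual_series)
      cur <- annual_series[n, ]
      prev <- annual_series[n - 1, ]
      tab <- yoy_change(cur, prev)
      ci_cur <- composite_index(cur)
      ci_prev <- composite_index(prev)
      list(table = tab,
           composite_current = ci_cur$index_2dp,
           composite_previous = ci_prev$index_2dp,
           composite_change = round_half_up(
             (ci_cur$index - ci_prev$index) / ci_prev$index * 100, 2))
    })

    bundle$trend <- run_stage("trend", {
      alpha <- config$trend$alpha %||% 0.05
      rows <- lapply(colnames(annual_series), function(nm) {
        tt <- spearman_trend(annual_series[, nm], alpha)
        data.frame(indicator = nm, rs = tt$rs, n = tt$n, w_p = tt$w_p,
                   significant = tt$significant, direction = tt$direction,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })

    bundle$gm11 <- run_stage("gm11", {
      horizon <- gm_cfg$horizon %||% 3L
      thr <- unlist(gm_cfg$thresholds)
      per <- lapply(colnames(annual_series), function(nm) {
        fit <- fit_gm11(annual_series[, nm])
        acc <- gm11_accuracy(fit)
        fc <- forecast_gm11(fit, horizon,
                            if (nm %in% names(thr)) thr[nm] else NULL)
        band <- relative_error_band(fit)
        list(indicator = nm, a = fit$a, u = fit$u, c = acc$c, p = acc$p,
             grade = acc$grade, forecast = fc$forecast,
             error_band = band,
             exceeds = if (!is.null(fc$exceeds)) fc$exceeds[, 1] else NULL)
      })
      names(per) <- colnames(annual_series)
      summary <- do.call(rbind, lapply(per, function(x) {
        data.frame(indicator = x$indicator, a = x$a, u = x$u, c = x$c,
                   p = x$p, grade = x$grade, stringsAsFactors = FALSE)
      }))
      list(summary = summary, models = per)
    })
  } else {
    bundle$comparison <- bundle$trend <- bundle$gm11 <- annual_series
  }

  bundle$correlations <- run_stage("correlations", {
    met <- gen_met_series(default_met_signs(),
                          n_months = config$met_months %||% 84,
                          strength = config$met_strength %||% 0.8,
                          seed = seed)
    mm <- if (!stage_failed(bundle$aqi)) bundle$aqi$monthly_means else NULL
    pollutant_matrix <- if (!is.null(mm)) {
      pearson_matrix(mm[, setdiff(names(mm), "month"), drop = FALSE])
    } else NULL
    list(met_matrix = pearson_matrix(met), pollutant_matrix = pollutant_matrix)
  })

  gra_cfg <- config$gra %||% list()
  bundle$gra <- run_stage("gra", {
    if (is.null(gra_cfg$reference)) stop("no grey-relational series configured")
    yrs <- unlist(gra_cfg$years)
    ref <- gen_annual_gm_series(gra_cfg$reference$a, gra_cfg$reference$u,
                                gra_cfg$reference$x1, length(yrs), 0)
    comps <- as.data.frame(lapply(gra_cfg$comparisons, function(s) {
      gen_annual_gm_series(s$a, s$u, s$x1, length(yrs), 0)
    }))
    names(comps) <- vapply(gra_cfg$comparisons, `[[`, character(1), "name")
    g <- grey_relational(ref, comps, gra_cfg$xi %||% 0.5)
    list(reference = gra_cfg$reference$name %||% "reference",
         degrees = g$degrees, ranking = rank_factors(g$degrees),
         m = g$m, M = g$M, xi = g$xi)
  })

  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("oasisaq report bundle (seed ", x$provenance$seed, ", year ",
      x$provenance$year, ")\n", sep = "")
  for (s in setdiff(names(x), "provenance")) {
    ok <- is.null(x[[s]]$error)
    cat(sprintf("  %-12s %s\n", s, if (ok) "ok" else paste("FAILED:", x[[s]]$error)))
  }
  invisible(x)
}

# Strip bulky per-day tables for the JSON summary; CSVs carry the details.
bundle_for_json <- function(bundle) {
  out <- bundle
  if (!stage_failed(out$aqi)) {
    out$aqi$results <- NULL
    out$aqi$summary$primary_days <- as.list(out$aqi$summary$primary_days)
  }
  if (!stage_failed(out$dust)) out$dust$flags <- NULL
  out
}

#' Write a report bundle to disk
#'
#' Emits stable, idempotent files: CSV tables (`aqi_results.csv`,
#' `dust_flags.csv`, `comparison.csv`, `trend.csv`, `gm11_summary.csv`,
#' `gra_degrees.csv`) plus a single `report.json` summary.  Rewriting the
#' same bundle produces byte-identical files.
#'
#' @param bundle a `report_bundle` from [run_analysis()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  paths <- character()
  put_csv <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!stage_failed(bundle$aqi)) put_csv(bundle$aqi$results, "aqi_results.csv")
  if (!stage_failed(bundle$dust)) put_csv(bundle$dust$flags, "dust_flags.csv")
  if (!stage_failed(bundle$comparison) && !is.null(bundle$comparison$table)) {
    put_csv(bundle$comparison$table, "comparison.csv")
  }
  if (!stage_failed(bundle$trend) && is.data.frame(bundle$trend)) {
    put_csv(bundle$trend, "trend.csv")
  }
  if (!stage_failed(bundle$gm11) && !is.null(bundle$gm11$summary)) {
    put_csv(bundle$gm11$summary, "gm11_summary.csv")
  }
  if (!stage_failed(bundle$gra) && !is.null(bundle$gra$degrees)) {
    put_csv(data.frame(indicator = names(bundle$gra$degrees),
                       degree = as.numeric(bundle$gra$degrees)),
            "gra_degrees.csv")
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(bundle_for_json(bundle), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       na = "null", force = TRUE)
  invisible(c(paths, jp))
}
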