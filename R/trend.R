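# Spearman rank trend testing of annual indicator series against tabulated
# critical values, Pearson correlation matrices with significance marks, and
# heating vs non-heating period split analyses.

#' Spearman rank correlation against time order
#'
#' Ranks the values ascending (average ranks for ties), takes time ranks
#' 1..n, and computes
#' \deqn{r_s = 1 - 6 \sum d_i^2 / (n (n^2 - 1)).}
#'
#' @param values annual indicator series in time order (n >= 3).
#' @return `rs` in \[-1, 1\]; `NA` with a warning for a constant series.
#' @examples
#' spearman_rs(c(3, 1, 2)) # -0.5
#' @export
spearman_rs <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 time periods")
  if (anyNA(values)) stop("missing values not allowed in trend series")
  if (length(unique(values)) == 1L) {
    warning("constant series: rank trend undefined")
    return(NA_real_)
  }
  d <- rank(values, ties.method = "average") - seq_len(n)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Significance decision for a rank trend
#'
#' Compares |rs| with the two-tailed critical value W_P for the series
#' length: the trend is significant when |rs| >= W_P, with direction given
#' by the sign of rs.
#'
#' @param rs rank correlation coefficient.
#' @param n series length (must be covered by the critical-value table).
#' @param alpha 0.05 (default) or 0.01.
#' @param table critical values, default [spearman_critical()].
#' @return list of class `trend_result`: `rs`, `n`, `alpha`, `w_p`,
#'   `significant`, `direction` ("up"/"down"/"none").
#' @export
trend_test <- function(rs, n, alpha = 0.05, table = spearman_critical()) {
  col <- if (isTRUE(all.equal(alpha, 0.05))) "alpha_05"
         else if (isTRUE(all.equal(alpha, 0.01))) "alpha_01"
         else stop("alpha must be 0.05 or 0.01")
  i <- match(n, table$n)
  if (is.na(i) || is.na(table[[col]][i])) {
    stop("no tabulated critical value for n = ", n, " at alpha = ", alpha)
  }
  w_p <- table[[col]][i]
  sig <- !is.na(rs) && abs(rs) >= w_p
  structure(list(
    rs = rs, n = n, alpha = alpha, w_p = w_p, significant = sig,
    direction = if (!sig) "none" else if (rs > 0) "up" else "down"
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("rs = %.3f (n = %d), W_P = %.3f at alpha = %.2f: %s%s\n",
              x$rs, x$n, x$w_p, x$alpha,
              if (x$significant) "significant" else "not significant",
              if (x$direction == "none") "" else paste0(", ", x$direction)))
  invisible(x)
}

#' Rank trend test of an annual series
#'
#' Convenience wrapper: [spearman_rs()] followed by [trend_test()].
#'
#' @inheritParams spearman_rs
#' @inheritParams trend_test
#' @return see [trend_test()].
#' @export
spearman_trend <- function(values, alpha = 0.05, table = spearman_critical()) {
  trend_test(spearman_rs(values), length(values), alpha, table)
}

#' Pearson correlation matrix with significance marks
#'
#' Pairwise Pearson correlations with two-sided t-test marks: `**` at the
#' 0.01 level, `*` at 0.05.  Zero-variance variables are flagged and their
#' pairs set to `NA`.
#'
#' @param x data.frame or matrix of numeric series (columns = variables),
#'   at least 3 complete observations per pair.
#' @return list of class `corr_matrix`: `r`, `p`, `marks` (character
#'   matrix), `n`.
#' @export
pearson_matrix <- function(x) {
  x <- as.data.frame(x)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  k <- ncol(x)
  if (k < 2) stop("need at least two numeric variables")
  vars <- names(x)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  marks <- matrix("", k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- complete.cases(x[[i]], x[[j]])
      if (sum(ok) < 3) stop("fewer than 3 paired observations for ",
                            vars[i], " vs ", vars[j])
      if (sd(x[[i]][ok]) == 0 || sd(x[[j]][ok]) == 0) {
        warning("zero variance in pair ", vars[i], " vs ", vars[j])
        next
      }
      ct <- cor.test(x[[i]][ok], x[[j]][ok])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      m <- if (ct$p.value < 0.01) "**" else if (ct$p.value < 0.05) "*" else ""
      marks[i, j] <- marks[j, i] <- m
    }
  }
  structure(list(r = r, p = p, marks = marks, n = nrow(x)),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, digits = 3, ...) {
  disp <- matrix(paste0(format(round(x$r, digits)), x$marks),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA"
  print(disp, quote = FALSE)
  invisible(x)
}

#' Heating vs non-heating split analysis
#'
#' Labels each day by the October 10 - April 10 heating rule, aggregates the
#' value per group within each period, and relates the paired heating and
#' non-heating aggregates by a Pearson correlation and simple linear fit
#' (for which the coefficient of determination is exactly r squared).
#'
#' @param daily data.frame with columns `date`, `value` and a pairing
#'   `group` (e.g. station, month-of-year, or year); groups present in both
#'   periods form the pairs.
#' @param fun aggregation function within period and group; default `mean`.
#' @return list of class `heating_split`: `pairs` (group, heating,
#'   non_heating), `r`, `r_squared`, `median_ratio` (heating median /
#'   non-heating median over pairs), `labels` (per input day).
#' @export
heating_split <- function(daily, fun = mean) {
  stopifnot(all(c("date", "value", "group") %in% names(daily)))
  lab <- heating_label(daily$date)
  agg <- function(on) {
    d <- daily[lab == on & !is.na(daily$value), ]
    tapply(d$value, d$group, fun)
  }
  h <- agg(TRUE)
  nh <- agg(FALSE)
  groups <- intersect(names(h), names(nh))
  if (length(groups) < 3) stop("need at least 3 paired groups per period")
  pairs <- data.frame(group = groups, heating = as.numeric(h[groups]),
                      non_heating = as.numeric(nh[groups]),
                      stringsAsFactors = FALSE)
  r <- cor(pairs$heating, pairs$non_heating)
  structure(list(
    pairs = pairs, r = r, r_squared = r^2,
    median_ratio = stats::median(pairs$heating) / stats::median(pairs$non_heating),
    labels = lab
  ), class = "heating_split")
}

#' @export
print.heating_split <- function(x, ...) {
  cat(sprintf("Heating vs non-heating: %d pairs, r = %.3f, R^2 = %.3f, median ratio %.2f\n",
              nrow(x$pairs), x$r, x$r_squared, x$median_ratio))
  invisible(x)
}
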