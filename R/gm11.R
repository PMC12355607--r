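# GM(1,1) grey forecasting.  The grey difference (even) form
#   x0(k) + a * z1(k) = u,  z1(k) = (x1(k) + x1(k-1)) / 2,
# is fitted by least squares over k = 2..n on the 1-AGO series x1 = cumsum(x0).
# Fitted and forecast values solve that difference equation exactly:
#   x1_hat(k) = (x0(1) - u/a) * beta^(k-1) + u/a,  beta = (1 - a/2)/(1 + a/2),
# restored by first differences with x0_hat(1) = x0(1).  beta is the discrete
# counterpart of exp(-a); solving the difference equation (rather than the
# continuous whitening equation) makes the fit exact on any series that
# satisfies the grey equation, e.g. geometric series.

#' Fit a GM(1,1) grey model
#'
#' @param x0 positive original series, length >= 4.
#' @return object of class `gm11`: `x0`, `x1` (AGO), `z1` (background
#'   values), `a` (development coefficient), `u` (grey action quantity),
#'   `beta`, `fitted` (restored values, `fitted[1] = x0[1]`), `residuals`
#'   (`x0 - fitted`; diagnostics use k = 2..n).
#' @examples
#' fit_gm11(c(100, 90, 81, 72.9, 65.61)) # exact: a = 2/19, u = 2000/19
#' @export
fit_gm11 <- function(x0) {
  x0 <- as.numeric(x0)
  n <- length(x0)
  if (n < 4) stop("GM(1,1) needs at least 4 observations")
  if (anyNA(x0) || any(x0 <= 0)) {
    stop("GM(1,1) requires a strictly positive series (AGO monotonicity)")
  }
  x1 <- cumsum(x0)
  z1 <- (x1[-1] + x1[-n]) / 2
  B <- cbind(-z1, 1)
  y <- x0[-1]
  xtx <- crossprod(B)
  if (abs(det(xtx)) < 1e-12 * max(abs(xtx))^2) {
    stop("singular normal equations in GM(1,1) fit")
  }
  coefs <- unname(drop(solve(xtx, crossprod(B, y))))
  a <- coefs[1]
  u <- coefs[2]
  beta <- (1 - a / 2) / (1 + a / 2)
  fitted <- gm11_restored(x0[1], a, u, n)
  structure(list(x0 = x0, x1 = x1, z1 = z1, a = a, u = u, beta = beta,
                 fitted = fitted, residuals = x0 - fitted),
            class = "gm11")
}

# Restored series of length n from the exact solution of the grey difference
# equation; a = 0 degenerates to the constant u after the first point.
gm11_restored <- function(x0_1, a, u, n) {
  if (abs(a) < 1e-12) return(c(x0_1, rep(u, n - 1L)))
  beta <- (1 - a / 2) / (1 + a / 2)
  k <- seq_len(n)
  x1_hat <- (x0_1 - u / a) * beta^(k - 1) + u / a
  c(x0_1, diff(x1_hat))
}

#' @export
print.gm11 <- function(x, ...) {
  cat(sprintf("GM(1,1): a = %.4f, u = %.4f (n = %d)\n",
              x$a, x$u, length(x$x0)))
  invisible(x)
}

# Grade from the posterior-variance thresholds; the overall grade is the
# worse of the p-grade and the c-grade.
#' Accuracy grade from posterior-variance diagnostics
#'
#' Grade 1 requires p >= 0.95 and c <= 0.35; grade 2: p >= 0.80 and
#' c <= 0.50; grade 3: p >= 0.70 and c <= 0.65; otherwise grade 4.
#'
#' @param c mean-square-error ratio (residual SD / data SD).
#' @param p small-error probability.
#' @return integer grade 1-4.
#' @export
gm11_grade <- function(c, p) {
  cg <- if (c <= 0.35) 1L else if (c <= 0.50) 2L else if (c <= 0.65) 3L else 4L
  pg <- if (p >= 0.95) 1L else if (p >= 0.80) 2L else if (p >= 0.70) 3L else 4L
  max(cg, pg)
}

#' Posterior-variance accuracy report
#'
#' Computes S1 (population SD of the original series), S2 (population SD of
#' the residuals over k = 2..n), the mean-square-error ratio c = S2/S1, the
#' small-error probability p = P(|e(k) - mean(e)| < 0.6745 S1), per-point
#' relative errors, and the accuracy grade.
#'
#' @param model fitted `gm11` object.
#' @return list of class `gm11_accuracy`: `s1`, `s2`, `c`, `p`,
#'   `relative_errors` (percent, k = 2..n), `grade`, `grade_label`.
#' @export
gm11_accuracy <- function(model) {
  stopifnot(inherits(model, "gm11"))
  x0 <- model$x0
  e <- model$residuals[-1]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  s1 <- pop_sd(x0)
  s2 <- pop_sd(e)
  if (s1 == 0) {
    if (s2 > 0) stop("degenerate model: constant series with non-zero residuals")
    c_ratio <- 0
    p <- 1
  } else {
    c_ratio <- s2 / s1
    p <- mean(abs(e - mean(e)) < 0.6745 * s1)
  }
  grade <- gm11_grade(c_ratio, p)
  structure(list(
    s1 = s1, s2 = s2, c = c_ratio, p = p,
    relative_errors = abs(e) / x0[-1] * 100,
    grade = grade,
    grade_label = c("first-order (good)", "second-order (qualified)",
                    "third-order (barely qualified)",
                    "fourth-order (unqualified)")[grade]
  ), class = "gm11_accuracy")
}

#' @export
print.gm11_accuracy <- function(x, ...) {
  cat(sprintf("GM(1,1) accuracy: c = %.4f, p = %.3f -> grade %d, %s\n",
              x$c, x$p, x$grade, x$grade_label))
  invisible(x)
}

#' Forecast from a fitted GM(1,1) model
#'
#' Extends the restored series h steps beyond the sample.  For a positive
#' series the forecasts are strictly increasing when a < 0 and strictly
#' decreasing when a > 0 (constant at u when a = 0).  Optional thresholds
#' are checked against each forecast step.
#'
#' @param model fitted `gm11` object.
#' @param h forecast horizon (>= 1).
#' @param thresholds optional named numeric vector; for each threshold the
#'   forecast steps exceeding it are reported.
#' @return list of class `gm11_forecast`: `forecast` (length h),
#'   `steps` (1..h), and `exceeds` (logical matrix h x length(thresholds)).
#' @export
forecast_gm11 <- function(model, h, thresholds = NULL) {
  stopifnot(inherits(model, "gm11"), h >= 1)
  n <- length(model$x0)
  full <- gm11_restored(model$x0[1], model$a, model$u, n + h)
  fc <- full[(n + 1):(n + h)]
  out <- list(forecast = fc, steps = seq_len(h))
  if (!is.null(thresholds)) {
    out$exceeds <- vapply(thresholds, function(t) fc > t, logical(h))
    if (h == 1) out$exceeds <- matrix(out$exceeds, nrow = 1,
                                      dimnames = list(NULL, names(thresholds)))
  }
  class(out) <- "gm11_forecast"
  out
}

#' Relative in-sample error band
#'
#' Minimum and maximum per-point relative error (percent) of the fit over
#' k = 2..n.
#'
#' @param model fitted `gm11` object.
#' @return numeric vector `c(min, max)` in percent.
#' @export
relative_error_band <- function(model) {
  stopifnot(inherits(model, "gm11"))
  re <- abs(model$residuals[-1]) / model$x0[-1] * 100
  c(min = min(re), max = max(re))
}
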