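# Grey relational analysis: normalize each sequence by its first element
# (initial image), take absolute differences from the reference, form
# relational coefficients with distinguishing coefficient xi, and average
# over time to the relational degree per comparison sequence.

#' Initial image of a sequence
#'
#' Scale-free normalization dividing a sequence by its first element, so
#' every normalized sequence starts at 1.
#'
#' @param x numeric sequence with `x[1] != 0`.
#' @param name optional name used in error messages.
#' @return numeric vector `x / x[1]`.
#' @examples
#' initial_image(c(2, 4, 8)) # 1 2 4
#' @export
initial_image <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (is.na(x[1]) || x[1] == 0) {
    stop("first element of sequence '", name, "' must be non-zero")
  }
  x / x[1]
}

#' Grey relational degrees
#'
#' For reference sequence X0 and comparison sequences Xi (all normalized to
#' initial images), computes difference sequences
#' \eqn{\Delta_i(k) = |x_0'(k) - x_i'(k)|}, the two-level extremes
#' \eqn{m = \min_i \min_k \Delta_i(k)} and \eqn{M = \max_i \max_k}, the
#' relational coefficients
#' \deqn{\gamma_{0i}(k) = (m + \xi M) / (\Delta_i(k) + \xi M)}
#' and the relational degree \eqn{\gamma_{0i}} as their mean over k.
#' When every comparison equals the reference (M = 0) all coefficients are
#' defined as 1.
#'
#' @param reference numeric reference sequence (length n, first element
#'   non-zero).
#' @param comparisons data.frame/matrix with one column per comparison
#'   sequence, or a single numeric vector.
#' @param xi distinguishing coefficient in (0, 1); default 0.5.
#' @return list of class `gra`: `images` (reference first), `delta`, `m`,
#'   `M`, `xi`, `coefficients` (n x m matrix) and `degrees` (named).
#' @export
grey_relational <- function(reference, comparisons, xi = 0.5) {
  if (!(xi > 0 && xi < 1)) stop("xi must lie in (0, 1)")
  comp <- as.data.frame(comparisons)
  if (is.null(names(comp)) || any(names(comp) == "")) {
    names(comp) <- paste0("X", seq_along(comp))
  }
  n <- length(reference)
  if (any(vapply(comp, length, integer(1)) != n)) {
    stop("all sequences must have the reference's length (", n, ")")
  }
  if (anyNA(reference) || anyNA(as.matrix(comp))) {
    stop("missing values are not allowed in grey relational analysis")
  }
  ref <- initial_image(reference, "reference")
  images <- vapply(names(comp), function(nm) initial_image(comp[[nm]], nm),
                   numeric(n))
  delta <- abs(images - ref)
  M <- max(delta)
  m <- min(delta)
  coef <- if (M == 0) {
    matrix(1, n, ncol(comp), dimnames = dimnames(delta))
  } else {
    (m + xi * M) / (delta + xi * M)
  }
  degrees <- colMeans(coef)
  structure(list(images = cbind(reference = ref, images), delta = delta,
                 m = m, M = M, xi = xi, coefficients = coef,
                 degrees = degrees), class = "gra")
}

#' @export
print.gra <- function(x, ...) {
  cat(sprintf("Grey relational analysis (xi = %.2f, m = %.4g, M = %.4g)\n",
              x$xi, x$m, x$M))
  print(round(x$degrees, 4))
  invisible(x)
}

#' Rank driver factors by relational degree
#'
#' Descending order of grey relational degrees; ties keep input order.
#'
#' @param degrees named numeric vector (e.g. `$degrees` of
#'   [grey_relational()]).
#' @return character vector of factor names, strongest association first.
#' @export
rank_factors <- function(degrees) {
  if (!length(degrees)) stop("no degrees to rank")
  names(degrees)[order(-as.numeric(degrees))]
}
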