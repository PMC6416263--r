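#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation on average-ranked data, with the p-value from the
#' t-distribution approximation and a confidence interval from the Fisher
#' z-transform.
#'
#' @param x,y numeric vectors of equal length (at least 3), neither
#'   constant.
#' @param conf confidence level for the interval, default 0.95.
#' @return list with elements `rho`, `p`, `ci` (length-2), and `n`.
#' @examples
#' spearmanRho(1:4, c(2, 2, 3, 4))
#' @export
spearmanRho <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
    ci <- c(rho, rho)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  }
  list(rho = rho, p = p, ci = ci, n = n)
}

#' Absolute percent change relative to a designated baseline
#'
#' `100 * |value - reference| / |reference|`; the reference is always the
#' baseline arm of the comparison (the STL value, the 2 mm-slice value,
#' the original-mask value, or the unscaled-volume value).
#'
#' @param value measured value(s).
#' @param reference baseline value(s), non-zero (recycled).
#' @return percent change(s), non-negative.
#' @examples
#' percentChange(110, 100) # 10
#' @export
percentChange <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * abs(value - reference) / abs(reference)
}
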