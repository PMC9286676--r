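#' Wilcoxon signed-rank test (paired, two-sided)
#'
#' Self-contained signed-rank test on paired differences. Zero differences
#' are dropped (with the usual reduction of n). When at most `exactLimit`
#' nonzero differences remain and their absolute values are tie-free, the
#' p-value comes from the exact null distribution of the V statistic;
#' otherwise from a normal approximation with tie correction and a 0.5
#' continuity correction.
#'
#' @param x,y Paired numeric vectors; alternatively pass the differences as
#'   `x` and leave `y = NULL`.
#' @param exactLimit Maximum n for the exact null (default 25).
#' @return List with `statistic` (V), `p`, `n` (nonzero pairs), and
#'   `exact` (logical).
#' @export
#' @examples
#' wilcoxonSignedRank(c(2, 3, 5), c(1, 1, 1))$p
wilcoxonSignedRank <- function(x, y = NULL, exactLimit = 25L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("non-finite differences")
  zeroes <- d == 0
  d <- d[!zeroes]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p = 1, n = 0L, exact = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && !any(zeroes) && n <= exactLimit) {
    p <- if (V > n * (n + 1) / 4) {
      psignrank(V - 1, n, lower.tail = FALSE)
    } else {
      psignrank(V, n)
    }
    return(list(statistic = V, p = min(2 * p, 1), n = n, exact = TRUE))
  }
  z <- V - n * (n + 1) / 4
  tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  if (sigma2 <= 0)
    return(list(statistic = V, p = 1, n = n, exact = FALSE))
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
  list(statistic = V, p = min(p, 1), n = n, exact = FALSE)
}

#' Wilcoxon rank-sum test (two-sample, two-sided)
#'
#' Self-contained Mann-Whitney/rank-sum test. With tie-free data and a
#' combined sample size of at most `exactLimit`, the p-value comes from the
#' exact null distribution of the U statistic; otherwise from a normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exactLimit Maximum combined n for the exact null (default 50).
#' @return List with `statistic` (U for sample `x`), `p`, and `exact`.
#' @export
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p  # exact 1/3
wilcoxonRankSum <- function(x, y, exactLimit = 50L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("non-finite values")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && nx + ny <= exactLimit) {
    p <- if (U > nx * ny / 2) {
      pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    } else {
      pwilcox(U, nx, ny)
    }
    return(list(statistic = U, p = min(2 * p, 1), exact = TRUE))
  }
  z <- U - nx * ny / 2
  tab <- table(r)
  sigma2 <- (nx * ny / 12) *
    ((nx + ny + 1) - sum(tab^3 - tab) / ((nx + ny) * (nx + ny - 1)))
  if (sigma2 <= 0)
    return(list(statistic = U, p = 1, exact = FALSE))
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
  list(statistic = U, p = min(p, 1), exact = FALSE)
}

#' Log2 fold change between two expression vectors
#'
#' Default convention (`mode = "expm1"`): de-log the log-normalized values,
#' average, add a pseudocount of 1 and take the log2 ratio,
#' \eqn{\log_2\frac{\overline{e^{a}-1} + 1}{\overline{e^{b}-1} + 1}} —
#' the convention of the mainstream single-cell toolkit. `mode = "logdiff"`
#' instead returns the difference of mean log-normalized values converted
#' to log2 units.
#'
#' @param a,b Numeric vectors of log-normalized (natural log) expression.
#' @param mode `"expm1"` (default) or `"logdiff"`.
#' @return A finite numeric scalar.
#' @export
log2FoldChange <- function(a, b, mode = c("expm1", "logdiff")) {
  mode <- match.arg(mode)
  if (mode == "expm1") {
    log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))
  } else {
    (mean(a) - mean(b)) / log(2)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' preserving input order. Thin validated wrapper around the standard
#' implementation.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
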