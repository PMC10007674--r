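# Shared input check for the aggregation operators. Scores live in the unit
# hypercube; softmax exports rounded to few decimals can stray by ~1e-16..1e-9,
# which is clamped (with a warning) when clamp = TRUE. Larger violations are
# always hard errors.
checkScores <- function(x, clamp = TRUE, tol = 1e-9) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x))
    stop("x must be a non-empty numeric vector without NA")
  lo <- min(x); hi <- max(x)
  if (lo < -tol || hi > 1 + tol)
    stop(sprintf("score out of range [0,1]: %g", if (lo < -tol) lo else hi))
  if (lo < 0 || hi > 1) {
    if (!clamp)
      stop(sprintf("score out of range [0,1]: %g", if (lo < 0) lo else hi))
    warning(sprintf("clamped %d score(s) marginally outside [0,1]",
                    sum(x < 0 | x > 1)))
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

#' Discrete Choquet integral with respect to a symmetric measure
#'
#' Computes \eqn{C_m(x) = \sum_{i=1}^{n} (x_{(i)} - x_{(i-1)})\, m(A_{(i)})},
#' where \eqn{x_{(1)} \le \dots \le x_{(n)}} is the increasing sort of
#' \code{x}, \eqn{x_{(0)} = 0}, and \eqn{A_{(i)}} is the set of indices of
#' the \eqn{n - i + 1} largest components — for a symmetric measure simply
#' \code{measureValues(m)[n - i + 2]}. The integral is idempotent and
#' averaging: the result always lies between \code{min(x)} and \code{max(x)}.
#'
#' Ties in \code{x} are harmless: the difference \eqn{x_{(i)} - x_{(i-1)}}
#' vanishes at a tie, so the value does not depend on the tie order of the
#' (stable) sort. Accumulation runs in fixed ascending index order, making
#' results bit-reproducible. The degenerate \code{n = 1} case is the
#' identity, so single-view operation is the same code path.
#'
#' @param x numeric vector of scores in \code{[0, 1]}, one per view; its
#'   length must equal \code{nViews(m)}.
#' @param m a [CardinalityMeasure-class].
#' @param clamp if \code{TRUE} (default), components outside \code{[0, 1]} by
#'   at most \code{1e-9} — typical softmax rounding noise — are clamped with
#'   a warning; if \code{FALSE}, any violation errors. Violations beyond
#'   \code{1e-9} always error.
#' @return A single number in \code{[min(x), max(x)]}.
#' @examples
#' choquet(c(0.1, 0.5, 0.7, 0.9), powerMeasure(1, 4))  # arithmetic mean 0.55
#' choquet(c(0.2, 0.8), powerMeasure(2, 2))            # 0.2 + 0.6 * 0.25
#' @export
choquet <- function(x, m, clamp = TRUE) {
  validateMeasure(m)
  x <- checkScores(x, clamp = clamp)
  n <- m@n
  if (length(x) != n)
    stop(sprintf("length(x) = %d does not match measure n = %d",
                 length(x), n))
  xs <- sort.int(x, method = "shell")            # increasing permutation
  w <- m@values[seq.int(n + 1L, 2L)]             # m(A_(i)), i = 1..n
  d <- xs - c(0, xs[-n])                         # x_(i) - x_(i-1), x_(0) = 0
  acc <- 0
  for (i in seq_len(n)) acc <- acc + d[i] * w[i] # fixed accumulation order
  acc
}

#' Brute-force Choquet oracle (independent cross-check)
#'
#' Evaluates the algebraically equivalent form \eqn{\sum_i x_{(i)}\,
#' (m(A_{(i)}) - m(A_{(i+1)}))} with \eqn{m(A_{(n+1)}) = 0}, using a separate
#' sort and accumulation path from [choquet()]. Intended only for testing
#' (\code{n <= 12}); the two implementations must agree to within 1e-12.
#'
#' @inheritParams choquet
#' @return A single number in \code{[min(x), max(x)]}.
#' @export
choquetOracle <- function(x, m, clamp = TRUE) {
  validateMeasure(m)
  x <- checkScores(x, clamp = clamp)
  n <- m@n
  if (length(x) != n)
    stop(sprintf("length(x) = %d does not match measure n = %d",
                 length(x), n))
  if (n > 12L) stop("oracle is restricted to n <= 12")
  xs <- rev(sort.int(x, decreasing = TRUE))      # independent sorting route
  mA <- c(m@values[seq.int(n + 1L, 2L)], 0)      # m(A_(1)), ..., m(A_(n)), 0
  sum(xs * (mA[-(n + 1L)] - mA[-1L]))
}

#' Baseline aggregation operators
#'
#' Arithmetic mean, minimum or maximum of a score vector — the comparison
#' baselines for the fusion experiment. \code{mean} coincides with the
#' Choquet integral under \code{powerMeasure(q = 1, n)}.
#'
#' @param x numeric vector of scores in \code{[0, 1]}.
#' @param kind one of \code{"mean"}, \code{"min"}, \code{"max"}.
#' @inheritParams choquet
#' @return A single number.
#' @examples
#' baselineAggregate(c(0.1, 0.5, 0.7, 0.9), "mean")  # 0.55
#' @export
baselineAggregate <- function(x, kind = c("mean", "min", "max"),
                              clamp = TRUE) {
  kind <- match.arg(kind)
  x <- checkScores(x, clamp = clamp)
  switch(kind, mean = mean(x), min = min(x), max = max(x))
}
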