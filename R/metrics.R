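#' One-vs-rest confusion tallies
#'
#' Tallies per-class true positives, false positives and false negatives
#' from aligned vectors of true and predicted labels over a fixed class set.
#'
#' @param trueLabels,predictedLabels equal-length character vectors; every
#'   label must occur in \code{classLabels}.
#' @param classLabels character vector of all class names (defines class
#'   order in the output).
#' @return A [ConfusionCounts-class].
#' @examples
#' cc <- confusionCounts(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' cc
#' @export
confusionCounts <- function(trueLabels, predictedLabels, classLabels) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  classLabels <- as.character(classLabels)
  if (length(trueLabels) == 0L) stop("no samples")
  if (length(trueLabels) != length(predictedLabels))
    stop("trueLabels and predictedLabels must have equal length")
  if (anyDuplicated(classLabels)) stop("classLabels must be distinct")
  bad <- setdiff(unique(c(trueLabels, predictedLabels)), classLabels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  tf <- factor(trueLabels, levels = classLabels)
  pf <- factor(predictedLabels, levels = classLabels)
  tab <- table(tf, pf)                   # rows = truth, cols = prediction
  tp <- as.integer(diag(tab))
  fn <- as.integer(rowSums(tab)) - tp
  fp <- as.integer(colSums(tab)) - tp
  names(tp) <- names(fp) <- names(fn) <- classLabels
  new("ConfusionCounts", tp = tp, fp = fp, fn = fn,
      nSamples = length(trueLabels))
}

#' F-beta score
#'
#' \eqn{F_\beta = (1 + \beta^2)\,P\,R / (\beta^2 P + R)}: the weighted
#' harmonic combination of precision and recall. \eqn{\beta = 1} weighs them
#' equally (harmonic mean); \eqn{\beta = 0.5} favours precision; as
#' \eqn{\beta \to 0} the score tends to precision and as \eqn{\beta \to
#' \infty} to recall. Returns 0 when the denominator vanishes (\eqn{P = R =
#' 0}), avoiding NaN propagation.
#'
#' @param prec,rec precision and recall in \code{[0, 1]} (vectorised).
#' @param beta positive scalar weight.
#' @return Numeric, same length as \code{prec}/\code{rec}.
#' @examples
#' fBeta(0.8, 2 / 3, beta = 1)    # 0.7272...
#' fBeta(0.8, 2 / 3, beta = 0.5)  # 0.7692...
#' @export
fBeta <- function(prec, rec, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0)
    stop("beta must be a single positive number")
  if (anyNA(prec) || anyNA(rec) || any(prec < 0 | prec > 1) ||
      any(rec < 0 | rec > 1))
    stop("prec and rec must be in [0,1]")
  b2 <- beta^2
  den <- b2 * prec + rec
  ifelse(den > 0, (1 + b2) * prec * rec / den, 0)
}

#' Precision/recall/F-beta report from confusion counts
#'
#' Computes per-class precision \eqn{TP/(TP+FP)}, recall \eqn{TP/(TP+FN)} and
#' \eqn{F_\beta} for each requested \eqn{\beta}, plus their macro averages
#' (unweighted mean over classes). Any 0/0 ratio is defined as 0 and noted
#' via a message, so empty classes depress rather than poison the averages.
#'
#' @param counts a [ConfusionCounts-class].
#' @param betas positive reals; one F column per value, named
#'   \code{F<beta>}.
#' @return A \code{data.frame} with one row per class plus a final
#'   \code{"macro"} row; columns \code{class}, \code{Prec}, \code{Rec} and
#'   the F columns (default \code{F0.5}, \code{F1}). The macro row is the
#'   unweighted column mean of the per-class rows.
#' @examples
#' cc <- confusionCounts(rep(c("A", "B"), c(12, 10)),
#'                       rep(c("A", "B", "A", "B"), c(8, 4, 2, 8)),
#'                       c("A", "B"))
#' evaluateCounts(cc)
#' @export
evaluateCounts <- function(counts, betas = c(0.5, 1)) {
  if (!is(counts, "ConfusionCounts")) stop("counts must be ConfusionCounts")
  if (!is.numeric(betas) || length(betas) < 1L || any(is.na(betas)) ||
      any(betas <= 0))
    stop("betas must be positive numbers")
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn
  safeDiv <- function(num, den) ifelse(den > 0, num / den, 0)
  if (any(tp + fp == 0L) || any(tp + fn == 0L))
    message("0/0 precision or recall encountered; defined as 0")
  prec <- safeDiv(tp, tp + fp)
  rec <- safeDiv(tp, tp + fn)
  out <- data.frame(class = names(tp), Prec = as.numeric(prec),
                    Rec = as.numeric(rec), stringsAsFactors = FALSE)
  for (b in betas)
    out[[paste0("F", format(b, trim = TRUE))]] <-
      as.numeric(fBeta(prec, rec, b))
  macro <- data.frame(class = "macro", t(colMeans(out[, -1L, drop = FALSE])),
                      stringsAsFactors = FALSE, check.names = FALSE)
  rbind(out, macro)
}

#' Macro-averaged metrics as a named vector
#'
#' Convenience wrapper extracting the macro row of [evaluateCounts()] as a
#' named numeric vector (\code{Prec}, \code{Rec}, \code{F0.5}, \code{F1} by
#' default).
#'
#' @inheritParams evaluateCounts
#' @return Named numeric vector of macro-averaged metrics.
#' @export
macroMetrics <- function(counts, betas = c(0.5, 1)) {
  rep <- evaluateCounts(counts, betas)
  v <- unlist(rep[rep$class == "macro", -1L, drop = TRUE])
  v
}
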