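#' Symmetric (cardinality-based) fuzzy measure
#'
#' A fuzzy measure (capacity) on an index set of size \code{n} whose value
#' depends only on subset cardinality, stored as the vector
#' \code{values[k + 1] = m(X)} for any subset \code{X} with \code{|X| = k},
#' \code{k = 0, ..., n}. Symmetry is all the Choquet integral needs for the
#' power measure family; general 2^n capacity tables are deliberately not
#' modelled.
#'
#' Validity requires \code{values[1] == 0}, \code{values[n + 1] == 1}
#' (boundary conditions), entries in \code{[0, 1]}, and monotone
#' non-decreasing values (increasingness: for a symmetric measure
#' X subset-of Y reduces to monotonicity in cardinality).
#'
#' @slot n integer(1), number of elements (views) aggregated.
#' @slot values numeric(n + 1), measure of a subset of each cardinality.
#' @slot q numeric(1), the power-measure exponent when applicable,
#'   \code{NA_real_} for measures not of that family.
#' @slot label character(1), free-text provenance, e.g. \code{"power(q=1)"}.
#'
#' @seealso [powerMeasure()], [validateMeasure()], [choquet()]
#' @examples
#' powerMeasure(q = 2, n = 4)
#' @export
setClass("CardinalityMeasure",
  representation(n = "integer", values = "numeric", q = "numeric",
                 label = "character"),
  validity = function(object) {
    n <- object@n
    v <- object@values
    if (length(n) != 1L || is.na(n) || n < 1L)
      return("n must be a single integer >= 1")
    if (length(v) != n + 1L)
      return(sprintf("values must have length n + 1 = %d, got %d",
                     n + 1L, length(v)))
    if (anyNA(v)) return("values must not contain NA")
    if (v[1L] != 0) return("m(∅) ≠ 0: values[0] must be exactly 0")
    if (v[n + 1L] != 1) return("m(N) ≠ 1: values[n] must be exactly 1")
    if (any(v < 0 | v > 1)) {
      k <- which(v < 0 | v > 1)[1L] - 1L
      return(sprintf("value out of [0,1] at k=%d", k))
    }
    if (any(diff(v) < 0)) {
      k <- which(diff(v) < 0)[1L]  # first k with values[k] < values[k-1]
      return(sprintf("non-monotone at k=%d", k))
    }
    TRUE
  })

#' Per-capture multi-view class-score matrix
#'
#' One capture of the same plant (or other object) by \code{K} views/cameras:
#' a \code{C x K} matrix whose entry \code{[c, k]} is the probability of class
#' \code{c} reported by the classifier applied to view \code{k} (a softmax
#' column per view).
#'
#' @slot scores numeric C x K matrix, all entries in \code{[0, 1]}.
#' @slot classLabels character(C), distinct class names (row order defines
#'   class indices).
#' @slot viewIds character(K), distinct view identifiers.
#' @slot captureId character(1), identifier of the capture.
#'
#' @seealso [ViewScoreMatrix()], [fuseViews()]
#' @export
setClass("ViewScoreMatrix",
  representation(scores = "matrix", classLabels = "character",
                 viewIds = "character", captureId = "character"),
  validity = function(object) {
    s <- object@scores
    if (!is.numeric(s)) return("scores must be a numeric matrix")
    if (nrow(s) < 2L) return("C >= 2 required (at least two classes)")
    if (ncol(s) < 1L) return("K >= 1 required (at least one view)")
    if (anyNA(s)) return("scores must not contain NA")
    if (any(s < 0 | s > 1)) return("score out of range [0,1]")
    if (length(object@classLabels) != nrow(s))
      return("classLabels length must equal nrow(scores)")
    if (length(object@viewIds) != ncol(s))
      return("viewIds length must equal ncol(scores)")
    if (anyDuplicated(object@classLabels))
      return("classLabels must be distinct")
    if (anyDuplicated(object@viewIds)) return("viewIds must be distinct")
    TRUE
  })

#' Fused per-class scores and the consensus decision
#'
#' Result of aggregating a [ViewScoreMatrix-class] across views: one fused
#' score per class plus the decided (argmax) class. Fused scores are not
#' renormalised to sum to one; the decision depends only on their order.
#'
#' @slot fused named numeric(C), fused score per class, each in \code{[0, 1]}.
#' @slot decidedClass integer(1), 1-based index of the decided class.
#' @slot decidedLabel character(1).
#' @slot tieBroken logical(1), \code{TRUE} when several classes attained the
#'   maximum within tolerance and the lowest index was taken.
#' @slot captureId character(1).
#'
#' @seealso [fuseViews()], [selectClass()]
#' @export
setClass("FusedScores",
  representation(fused = "numeric", decidedClass = "integer",
                 decidedLabel = "character", tieBroken = "logical",
                 captureId = "character"),
  validity = function(object) {
    f <- object@fused
    if (length(f) < 1L) return("fused must be non-empty")
    if (anyNA(f)) return("fused must not contain NA")
    if (any(f < 0 | f > 1)) return("fused score out of [0,1]")
    d <- object@decidedClass
    if (length(d) != 1L || is.na(d) || d < 1L || d > length(f))
      return("decidedClass out of range")
    if (f[d] < max(f) - 1e-12)
      return("decidedClass does not attain the maximum fused score")
    TRUE
  })

#' Per-class confusion tallies
#'
#' One-vs-rest true-positive / false-positive / false-negative counts per
#' class, the sufficient statistics for precision, recall and F-beta. True
#' negatives are not tracked; no reported metric needs them.
#'
#' @slot tp,fp,fn named integer vectors, one entry per class.
#' @slot nSamples integer(1), total number of predictions tallied.
#'
#' @seealso [confusionCounts()], [evaluateCounts()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 nSamples = "integer"),
  validity = function(object) {
    C <- length(object@tp)
    if (C < 1L) return("at least one class required")
    if (length(object@fp) != C || length(object@fn) != C)
      return("tp, fp, fn must have equal length")
    if (is.null(names(object@tp))) return("counts must be named by class")
    if (any(object@tp < 0L) || any(object@fp < 0L) || any(object@fn < 0L))
      return("counts must be non-negative")
    if (sum(object@tp) > object@nSamples)
      return("sum of TP cannot exceed nSamples")
    TRUE
  })

#' Configuration of the multi-view output simulator
#'
#' Full specification of the synthetic generator of per-view softmax outputs.
#' A capture draws a true class uniformly; each view independently is
#' corrupted with probability \code{pCorrupt} (its column drawn from a flat
#' Dirichlet carrying no information about the truth) and otherwise drawn
#' from a Dirichlet with concentration \code{alphaNoise} on every class plus
#' \code{alphaSignal} added on the true class.
#'
#' @slot nClasses,nViews,nCaptures integers: class count (C), view count
#'   (K), captures per batch.
#' @slot regime character(1), \code{"clean"} or \code{"degraded"}.
#' @slot alphaSignal numeric(1) > 0, concentration boost on the true class.
#' @slot alphaNoise numeric(1) > 0, base concentration on all classes.
#' @slot pCorrupt numeric(1) in \code{[0, 1]}, per-view corruption rate.
#' @slot seed integer(1), root seed; per-capture streams derive from it.
#'
#' @seealso [simulationConfig()], [simulateBatch()]
#' @export
setClass("SimulationConfig",
  representation(nClasses = "integer", nViews = "integer",
                 nCaptures = "integer", regime = "character",
                 alphaSignal = "numeric", alphaNoise = "numeric",
                 pCorrupt = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nClasses < 2L) return("C >= 2 required")
    if (object@nViews < 1L) return("K >= 1 required")
    if (object@nCaptures < 1L) return("nCaptures >= 1 required")
    if (!object@regime %in% c("clean", "degraded"))
      return("regime must be 'clean' or 'degraded'")
    if (!is.finite(object@alphaSignal) || object@alphaSignal <= 0)
      return("alphaSignal must be > 0")
    if (!is.finite(object@alphaNoise) || object@alphaNoise <= 0)
      return("alphaNoise must be > 0")
    if (is.na(object@pCorrupt) || object@pCorrupt < 0 || object@pCorrupt > 1)
      return("pCorrupt must be in [0,1]")
    if (is.na(object@seed)) return("seed must be an integer")
    TRUE
  })

#' A simulated batch of labelled captures
#'
#' @slot matrices list of [ViewScoreMatrix-class], one per capture.
#' @slot trueLabels character, one true class label per capture.
#' @slot config the [SimulationConfig-class] that generated the batch.
#'
#' @seealso [simulateBatch()]
#' @export
setClass("LabeledBatch",
  representation(matrices = "list", trueLabels = "character",
                 config = "SimulationConfig"),
  validity = function(object) {
    n <- object@config@nCaptures
    if (length(object@matrices) != n || length(object@trueLabels) != n)
      return("matrices and trueLabels must both have length nCaptures")
    ok <- vapply(object@matrices, function(m) {
      is(m, "ViewScoreMatrix") &&
        nrow(m@scores) == object@config@nClasses &&
        ncol(m@scores) == object@config@nViews
    }, logical(1))
    if (!all(ok)) return("every matrix must be a C x K ViewScoreMatrix")
    TRUE
  })
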