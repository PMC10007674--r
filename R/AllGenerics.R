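#' Accessors for ChoquetFusion classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{measureValues} returns the cardinality-indexed vector of a
#' [CardinalityMeasure-class]; \code{nViews} the number of aggregated
#' elements/views; \code{classLabels} the class names of a score matrix or
#' batch; \code{viewIds} the view identifiers; \code{captureId} the capture
#' identifier; \code{fusedScores}, \code{decidedClass}, \code{decidedLabel}
#' and \code{tieBroken} the components of a [FusedScores-class];
#' \code{trueLabels} the ground truth of a [LabeledBatch-class].
#'
#' @param x an object of the appropriate class.
#' @return The accessed component (vector, scalar or list; see each class).
#' @examples
#' m <- powerMeasure(1, 4)
#' measureValues(m)
#' nViews(m)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("measureValues", function(x) standardGeneric("measureValues"))

#' @rdname accessors
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("viewIds", function(x) standardGeneric("viewIds"))

#' @rdname accessors
#' @export
setGeneric("captureId", function(x) standardGeneric("captureId"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("fusedScores", function(x) standardGeneric("fusedScores"))

#' @rdname accessors
#' @export
setGeneric("decidedClass", function(x) standardGeneric("decidedClass"))

#' @rdname accessors
#' @export
setGeneric("decidedLabel", function(x) standardGeneric("decidedLabel"))

#' @rdname accessors
#' @export
setGeneric("tieBroken", function(x) standardGeneric("tieBroken"))

#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

setMethod("measureValues", "CardinalityMeasure", function(x) x@values)
setMethod("nViews", "CardinalityMeasure", function(x) x@n)
setMethod("nViews", "ViewScoreMatrix", function(x) ncol(x@scores))
setMethod("classLabels", "ViewScoreMatrix", function(x) x@classLabels)
setMethod("classLabels", "LabeledBatch",
          function(x) classLabels(x@matrices[[1L]]))
setMethod("viewIds", "ViewScoreMatrix", function(x) x@viewIds)
setMethod("captureId", "ViewScoreMatrix", function(x) x@captureId)
setMethod("captureId", "FusedScores", function(x) x@captureId)
setMethod("scoreMatrix", "ViewScoreMatrix", function(x) {
  s <- x@scores
  dimnames(s) <- list(x@classLabels, x@viewIds)
  s
})
setMethod("fusedScores", "FusedScores", function(x) x@fused)
setMethod("decidedClass", "FusedScores", function(x) x@decidedClass)
setMethod("decidedLabel", "FusedScores", function(x) x@decidedLabel)
setMethod("tieBroken", "FusedScores", function(x) x@tieBroken)
setMethod("trueLabels", "LabeledBatch", function(x) x@trueLabels)
setMethod("simConfig", "LabeledBatch", function(x) x@config)
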