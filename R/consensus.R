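#' Construct a per-capture view-score matrix
#'
#' Wraps a \code{C x K} matrix of per-view class probabilities in a validated
#' [ViewScoreMatrix-class]. Each column is expected to be one view's softmax
#' output, so column sums are checked against 1 at a tolerance of
#' \code{1e-4}; real softmax exports are rounded, hence the check is
#' downgradeable to a warning or skipped.
#'
#' @param scores numeric \code{C x K} matrix, entries in \code{[0, 1]}; rows
#'   are classes, columns are views.
#' @param classLabels character(C), distinct class names; defaults to the
#'   matrix row names or \code{class01, ...}.
#' @param viewIds character(K), distinct view identifiers; defaults to the
#'   column names or \code{view1, ...}.
#' @param captureId identifier of the capture.
#' @param colSumCheck \code{"error"} (default), \code{"warn"} or
#'   \code{"none"}: what to do when a column does not sum to 1 within
#'   \code{colSumTol}.
#' @param colSumTol tolerance on \code{|colSums(scores) - 1|}.
#' @return A validated [ViewScoreMatrix-class].
#' @examples
#' s <- matrix(c(0.7, 0.2, 0.1, 0.6, 0.3, 0.1), ncol = 2)
#' ViewScoreMatrix(s, classLabels = c("healthy", "rust", "blight"))
#' @export
ViewScoreMatrix <- function(scores, classLabels = NULL, viewIds = NULL,
                            captureId = "capture1",
                            colSumCheck = c("error", "warn", "none"),
                            colSumTol = 1e-4) {
  colSumCheck <- match.arg(colSumCheck)
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(classLabels))
    classLabels <- rownames(scores) %||%
      sprintf("class%02d", seq_len(nrow(scores)))
  if (is.null(viewIds))
    viewIds <- colnames(scores) %||% sprintf("view%d", seq_len(ncol(scores)))
  dimnames(scores) <- NULL
  if (nrow(scores) < 2L) stop("C >= 2 required (at least two classes)")
  if (ncol(scores) < 1L) stop("K >= 1 required (at least one view)")
  if (colSumCheck != "none") {
    dev <- abs(colSums(scores) - 1)
    if (any(dev > colSumTol)) {
      k <- which.max(dev)
      msg <- sprintf(
        "column %d ('%s') sums to %.6f, not 1 within %g",
        k, viewIds[k], colSums(scores)[k], colSumTol)
      if (colSumCheck == "error") stop(msg) else warning(msg)
    }
  }
  new("ViewScoreMatrix", scores = scores,
      classLabels = as.character(classLabels),
      viewIds = as.character(viewIds),
      captureId = as.character(captureId)[1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consensus decision from fused scores
#'
#' Returns the argmax of the fused per-class scores — the "maximum response"
#' decision. When several classes attain the maximum within an absolute
#' tolerance of \code{1e-12}, the lowest class index wins and the tie is
#' flagged, making decisions deterministic.
#'
#' @param fused numeric vector of fused per-class scores in \code{[0, 1]}.
#' @param labels optional character vector of class labels (same length).
#' @return A list with \code{index} (1-based), \code{label} and
#'   \code{tieBroken}.
#' @examples
#' selectClass(c(0.1, 0.9, 0.05))   # index 2
#' selectClass(c(0.5, 0.5))         # index 1, tieBroken TRUE
#' @export
selectClass <- function(fused, labels = NULL) {
  if (!is.numeric(fused) || length(fused) < 1L || anyNA(fused))
    stop("fused must be a non-empty numeric vector without NA")
  if (is.null(labels)) labels <- sprintf("class%02d", seq_along(fused))
  if (length(labels) != length(fused))
    stop("labels must match fused in length")
  top <- which(fused >= max(fused) - 1e-12)
  idx <- top[1L]
  list(index = idx, label = labels[idx], tieBroken = length(top) > 1L)
}

#' Fuse the views of one capture with the Choquet integral
#'
#' For each class independently, the K per-view scores (one matrix row) are
#' sorted increasingly and aggregated by the Choquet integral with respect to
#' \code{m}; the consensus class is then the maximum fused response
#' ([selectClass()]). The fused vector is \emph{not} renormalised to sum to
#' one — the Choquet integral of softmax columns is generally not a
#' distribution, and the argmax decision only needs the order.
#'
#' By internality of the Choquet integral, every fused score lies between
#' that class's minimum and maximum across views, and with
#' \code{powerMeasure(1, K)} the fused vector is the per-class mean.
#'
#' @param mat a [ViewScoreMatrix-class].
#' @param m a [CardinalityMeasure-class] with \code{nViews(m)} equal to the
#'   number of views in \code{mat}.
#' @inheritParams choquet
#' @return A [FusedScores-class].
#' @examples
#' s <- matrix(c(0.2, 0.8, 0.8, 0.2), nrow = 2)  # two classes, two views
#' fusedScores(fuseViews(ViewScoreMatrix(s), powerMeasure(1, 2)))
#' @export
fuseViews <- function(mat, m, clamp = TRUE) {
  if (!is(mat, "ViewScoreMatrix")) stop("mat must be a ViewScoreMatrix")
  validateMeasure(m)
  s <- mat@scores
  K <- ncol(s)
  if (m@n != K)
    stop(sprintf("measure n = %d does not match view count K = %d", m@n, K))
  fused <- .choquetRows(s, m, clamp = clamp)
  names(fused) <- mat@classLabels
  sel <- selectClass(fused, mat@classLabels)
  new("FusedScores", fused = fused, decidedClass = as.integer(sel$index),
      decidedLabel = sel$label, tieBroken = sel$tieBroken,
      captureId = mat@captureId)
}

# Row-wise Choquet integral of a C x K matrix, vectorised across rows:
# sort within each row (order(row, value) is a stable within-row sort),
# difference against x_(0) = 0, and weight by m(A_(i)) = values[K - i + 2].
.choquetRows <- function(s, m, clamp = TRUE) {
  K <- ncol(s)
  x <- checkScores(as.vector(s), clamp = clamp)
  s <- matrix(x, nrow = nrow(s), ncol = K)
  if (K == 1L) return(s[, 1L])
  xs <- matrix(s[order(row(s), s)], ncol = K, byrow = TRUE)
  d <- xs - cbind(0, xs[, -K, drop = FALSE])
  w <- m@values[seq.int(K + 1L, 2L)]
  as.vector(d %*% w)
}

#' Apply a fusion mode to a batch of captures
#'
#' Runs the chosen decision rule on every capture of a batch and returns one
#' [FusedScores-class] per capture. Modes:
#' \describe{
#'   \item{\code{choquet}}{Choquet fusion with measure \code{m} (the
#'     consensus method).}
#'   \item{\code{single_view:k}}{the one-camera baseline: column \code{k}
#'     (1-based) taken unchanged, decision by its argmax.}
#'   \item{\code{mean}, \code{min}, \code{max}}{per-class
#'     [baselineAggregate()] across views.}
#' }
#' With \code{K = 1} Choquet fusion reduces to \code{single_view:1}; with
#' \code{powerMeasure(1, K)} it coincides with \code{mean}.
#'
#' @param matrices list of [ViewScoreMatrix-class] sharing class labels and
#'   view count.
#' @param m a [CardinalityMeasure-class]; required for mode
#'   \code{"choquet"}, ignored otherwise.
#' @param mode fusion mode string (see Details).
#' @inheritParams choquet
#' @return A list of [FusedScores-class], one per capture.
#' @export
predictBatch <- function(matrices, m = NULL, mode = "choquet",
                         clamp = TRUE) {
  if (is(matrices, "LabeledBatch")) matrices <- matrices@matrices
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("matrices must be a non-empty list of ViewScoreMatrix objects")
  ref <- matrices[[1L]]
  if (!is(ref, "ViewScoreMatrix")) stop("matrices must hold ViewScoreMatrix")
  labs <- ref@classLabels
  K <- ncol(ref@scores)
  ok <- vapply(matrices, function(x) {
    is(x, "ViewScoreMatrix") && identical(x@classLabels, labs) &&
      ncol(x@scores) == K
  }, logical(1))
  if (!all(ok))
    stop("all captures must share the same class labels and view count")

  if (identical(mode, "choquet")) {
    if (is.null(m)) stop("mode 'choquet' requires a measure m")
    return(lapply(matrices, fuseViews, m = m, clamp = clamp))
  }
  if (grepl("^single_view:[0-9]+$", mode)) {
    k <- as.integer(sub("^single_view:", "", mode))
    if (k < 1L || k > K)
      stop(sprintf("single_view index %d out of range 1..%d", k, K))
    colFun <- function(s) s[, k]
  } else if (mode %in% c("mean", "min", "max")) {
    colFun <- switch(mode,
      mean = function(s) rowMeans(s),
      min  = function(s) apply(s, 1L, min),
      max  = function(s) apply(s, 1L, max))
  } else {
    stop(sprintf("unknown fusion mode '%s'", mode))
  }
  lapply(matrices, function(mat) {
    s <- matrix(checkScores(as.vector(mat@scores), clamp = clamp),
                nrow = nrow(mat@scores))
    fused <- colFun(s)
    names(fused) <- labs
    sel <- selectClass(fused, labs)
    new("FusedScores", fused = fused, decidedClass = as.integer(sel$index),
        decidedLabel = sel$label, tieBroken = sel$tieBroken,
        captureId = mat@captureId)
  })
}
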