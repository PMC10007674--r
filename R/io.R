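#' Read view-score matrices from CSV
#'
#' Reads the score-matrix CSV dialect: a \code{class} column followed by one
#' numeric column per view id. A single file may hold one capture, or many
#' captures in long format with an additional \code{capture_id} column (the
#' first column). UTF-8, '.' decimal separator.
#'
#' @param path CSV file path.
#' @param colSumCheck,colSumTol passed to [ViewScoreMatrix()].
#' @return A list of [ViewScoreMatrix-class], one per capture, in file
#'   order.
#' @export
readScoreMatrices <- function(path, colSumCheck = "error",
                              colSumTol = 1e-4) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        comment.char = "#")
  if (!"class" %in% names(df))
    stop(sprintf("%s: missing required 'class' column", path))
  hasCapture <- "capture_id" %in% names(df)
  viewCols <- setdiff(names(df), c("class", "capture_id"))
  if (length(viewCols) < 1L)
    stop(sprintf("%s: no view columns found", path))
  for (v in viewCols) if (!is.numeric(df[[v]]))
    stop(sprintf("%s: view column '%s' is not numeric", path, v))
  groups <- if (hasCapture) split(df, factor(df$capture_id,
                                             levels = unique(df$capture_id)))
            else list(capture1 = df)
  lapply(names(groups), function(id) {
    g <- groups[[id]]
    ViewScoreMatrix(as.matrix(g[, viewCols, drop = FALSE]),
                    classLabels = g$class, viewIds = viewCols,
                    captureId = id, colSumCheck = colSumCheck,
                    colSumTol = colSumTol)
  })
}

#' Write view-score matrices to CSV
#'
#' Writes a list of captures (or a whole [LabeledBatch-class]) in the long
#' score-matrix dialect read by [readScoreMatrices()]. For a batch, a
#' companion labels file (\code{capture_id,true_label}) can be written too,
#' making the simulator a fixture generator for the rest of the pipeline.
#'
#' @param x a list of [ViewScoreMatrix-class] or a [LabeledBatch-class].
#' @param path output CSV path for the score matrices.
#' @param labelsPath optional path for the truth CSV (batches only).
#' @return \code{path}, invisibly.
#' @export
writeScoreMatrices <- function(x, path, labelsPath = NULL) {
  mats <- if (is(x, "LabeledBatch")) x@matrices else x
  rows <- lapply(mats, function(m) {
    data.frame(capture_id = m@captureId, class = m@classLabels,
               m@scores, check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("capture_id", "class", mats[[1L]]@viewIds)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(labelsPath)) {
    if (!is(x, "LabeledBatch"))
      stop("labelsPath requires a LabeledBatch")
    utils::write.csv(
      data.frame(capture_id = vapply(mats, captureId, character(1)),
                 true_label = x@trueLabels),
      labelsPath, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write consensus predictions
#'
#' Writes one row per capture with \code{capture_id}, \code{decided_label},
#' \code{tie_broken} and the fused score of every class. The JSON format
#' additionally records provenance (fusion mode, measure label and q).
#'
#' @param preds list of [FusedScores-class].
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param provenance named list recorded in the JSON header (ignored for
#'   CSV), e.g. \code{list(mode = "choquet", q = 1)}.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(preds, path, format = c("csv", "json"),
                             provenance = list()) {
  format <- match.arg(format)
  stopifnot(length(preds) >= 1L)
  labs <- names(preds[[1L]]@fused)
  df <- do.call(rbind, lapply(preds, function(p) {
    data.frame(capture_id = p@captureId, decided_label = p@decidedLabel,
               tie_broken = p@tieBroken,
               as.data.frame(as.list(p@fused), check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(list(provenance = provenance, predictions = df),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a predictions CSV
#'
#' @param path CSV written by [writePredictions()] (csv format).
#' @return The predictions \code{data.frame}.
#' @export
readPredictions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        comment.char = "#")
  need <- c("capture_id", "decided_label", "tie_broken")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  df
}

#' Evaluate predictions against a truth table
#'
#' Joins a predictions table to a truth table on \code{capture_id} and
#' computes the evaluation report. Capture ids present on one side only are
#' an error, listed in the message.
#'
#' @param predictions data.frame with \code{capture_id} and
#'   \code{decided_label} (as from [readPredictions()]).
#' @param truth data.frame with \code{capture_id} and \code{true_label}.
#' @param classLabels class set; defaults to all labels seen in either
#'   column.
#' @param betas passed to [evaluateCounts()].
#' @return The [evaluateCounts()] data.frame (per-class rows + macro row).
#' @export
evaluatePredictions <- function(predictions, truth, classLabels = NULL,
                                betas = c(0.5, 1)) {
  onlyP <- setdiff(predictions$capture_id, truth$capture_id)
  onlyT <- setdiff(truth$capture_id, predictions$capture_id)
  if (length(onlyP) || length(onlyT))
    stop("unmatched capture_id(s): ",
         paste(utils::head(c(onlyP, onlyT), 20L), collapse = ", "))
  i <- match(predictions$capture_id, truth$capture_id)
  tl <- as.character(truth$true_label[i])
  pl <- as.character(predictions$decided_label)
  if (is.null(classLabels)) classLabels <- sort(unique(c(tl, pl)))
  evaluateCounts(confusionCounts(tl, pl, classLabels), betas = betas)
}

#' Write an evaluation or experiment report
#'
#' @param report a data.frame (from [evaluateCounts()] or
#'   [runExperiment()]).
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param provenance named list echoed into the output (JSON header, or
#'   \code{#}-prefixed comment lines atop the CSV).
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path, format = c("csv", "json"),
                        provenance = list()) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (length(provenance))
      writeLines(sprintf("# %s: %s", names(provenance),
                         vapply(provenance,
                                function(v) paste(format(v), collapse = ","),
                                character(1))), con)
    utils::write.csv(report, con, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(provenance = provenance, report = report),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
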