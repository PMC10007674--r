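#' Power fuzzy measure
#'
#' Constructs the symmetric power measure \eqn{m_q(X) = (|X|/n)^q}, \eqn{q >
#' 0}, as a [CardinalityMeasure-class]. With \eqn{q = 1} the Choquet integral
#' with respect to this measure is the arithmetic mean; \eqn{q \to 0^+}
#' approaches the maximum and \eqn{q \to \infty} the minimum, so \code{q}
#' tunes the aggregation between optimistic and pessimistic consensus.
#'
#' The boundary values at cardinality 0 and \code{n} are set to exact 0 and 1
#' rather than computed through the power, so the measure satisfies its
#' boundary conditions with no floating-point drift.
#'
#' @param q positive exponent of the power measure.
#' @param n positive integer, number of elements (views) to aggregate.
#' @return A validated [CardinalityMeasure-class].
#' @examples
#' measureValues(powerMeasure(1, 4))    # 0 0.25 0.50 0.75 1
#' measureValues(powerMeasure(2, 4))    # 0 0.0625 0.25 0.5625 1
#' @export
powerMeasure <- function(q, n) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0)
    stop("q must be a single positive number (power measure requires q > 0)")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  v <- ((0:n) / n)^q
  v[1L] <- 0
  v[n + 1L] <- 1
  new("CardinalityMeasure", n = n, values = v, q = as.numeric(q),
      label = sprintf("power(q=%g)", q))
}

#' Construct a cardinality measure from raw values
#'
#' Builds a [CardinalityMeasure-class] directly from its cardinality-indexed
#' value vector, running the full validity check (boundary conditions,
#' monotonicity, range).
#'
#' @param values numeric of length \code{n + 1}; \code{values[k + 1]} is the
#'   measure of any subset of cardinality \code{k}.
#' @param label free-text provenance label.
#' @param q optional exponent to record when the values come from a power
#'   measure; \code{NA} otherwise.
#' @return A validated [CardinalityMeasure-class].
#' @export
cardinalityMeasure <- function(values, label = "custom", q = NA_real_) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("values must be numeric of length >= 2 (n >= 1)")
  new("CardinalityMeasure", n = length(values) - 1L,
      values = as.numeric(values), q = as.numeric(q),
      label = as.character(label)[1L])
}

#' Validate a cardinality measure
#'
#' Re-runs the fuzzy-measure invariants — \eqn{m(\emptyset) = 0}, \eqn{m(N) =
#' 1}, entries in \eqn{[0, 1]}, monotone non-decreasing in cardinality — and
#' returns the measure unchanged if all hold. Errors name the violated
#' property and the offending cardinality.
#'
#' @param m a [CardinalityMeasure-class].
#' @return \code{m}, invisibly unchanged, if valid.
#' @export
validateMeasure <- function(m) {
  if (!is(m, "CardinalityMeasure"))
    stop("m must be a CardinalityMeasure")
  msg <- validObject(m, test = TRUE)
  if (!isTRUE(msg)) stop(msg)
  m
}

#' Read and write measures as JSON
#'
#' Serialises a [CardinalityMeasure-class] to the JSON object
#' \code{{"n": int, "q": float|null, "values": [...], "label": str}}, and
#' back. Reading validates the measure.
#'
#' @param m a [CardinalityMeasure-class].
#' @param path file path; for \code{measureToJSON}, \code{NULL} returns the
#'   JSON string instead of writing.
#' @return \code{measureToJSON}: the path (or JSON string) invisibly;
#'   \code{measureFromJSON}: a validated [CardinalityMeasure-class].
#' @examples
#' txt <- measureToJSON(powerMeasure(2, 4))
#' measureFromJSON(txt)
#' @export
measureToJSON <- function(m, path = NULL) {
  validateMeasure(m)
  obj <- list(n = m@n, q = m@q, values = m@values, label = m@label)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null")
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname measureToJSON
#' @param json a JSON string or the path of a JSON file.
#' @export
measureFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json)
  q <- if (is.null(obj$q)) NA_real_ else as.numeric(obj$q)
  lab <- if (is.null(obj$label)) "from-json" else obj$label
  m <- cardinalityMeasure(obj$values, label = lab, q = q)
  if (!is.null(obj$n) && as.integer(obj$n) != m@n)
    stop(sprintf("declared n=%d does not match length(values)-1=%d",
                 as.integer(obj$n), m@n))
  m
}
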