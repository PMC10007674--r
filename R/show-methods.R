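setMethod("show", "CardinalityMeasure", function(object) {
  cat(sprintf("CardinalityMeasure '%s' on n = %d elements\n",
              object@label, object@n))
  v <- object@values
  cat("  m(|X|=k), k = 0..n: ",
      paste(format(v, digits = 4), collapse = " "), "\n", sep = "")
})

setMethod("show", "ViewScoreMatrix", function(object) {
  cat(sprintf("ViewScoreMatrix '%s': %d classes x %d views\n",
              object@captureId, nrow(object@scores), ncol(object@scores)))
  top <- order(rowMeans(object@scores), decreasing = TRUE)[1:min(3L,
                                                        nrow(object@scores))]
  for (c in top)
    cat(sprintf("  %-20s %s\n", object@classLabels[c],
                paste(format(object@scores[c, ], digits = 3),
                      collapse = " ")))
  if (nrow(object@scores) > 3L)
    cat(sprintf("  ... (%d more classes)\n", nrow(object@scores) - 3L))
})

setMethod("show", "FusedScores", function(object) {
  cat(sprintf("FusedScores '%s': decided '%s' (class %d%s)\n",
              object@captureId, object@decidedLabel, object@decidedClass,
              if (object@tieBroken) ", tie broken to lowest index" else ""))
  cat(sprintf("  fused score %.4f over %d classes\n",
              object@fused[object@decidedClass], length(object@fused)))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts over %d classes, %d samples\n",
              length(object@tp), object@nSamples))
  cat(sprintf("  total TP %d, FP %d, FN %d\n",
              sum(object@tp), sum(object@fp), sum(object@fn)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %s regime, C=%d K=%d nCaptures=%d seed=%d\n",
    object@regime, object@nClasses, object@nViews, object@nCaptures, object@seed))
  cat(sprintf("  alphaSignal=%g alphaNoise=%g pCorrupt=%g\n",
              object@alphaSignal, object@alphaNoise, object@pCorrupt))
})

setMethod("show", "LabeledBatch", function(object) {
  cat(sprintf("LabeledBatch: %d captures (%s regime, C=%d, K=%d)\n",
              length(object@matrices), object@config@regime,
              object@config@nClasses, object@config@nViews))
})
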