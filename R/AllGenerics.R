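#' Count trainable parameters
#'
#' Sums trainable parameters over the layer graph using standard layer
#' algebra: \code{k*c_in*c_out + c_out} for a convolution,
#' \code{k*c_in + c_in} for a depthwise convolution,
#' \code{n_in*n_out + n_out} for a dense layer; pooling, activation, flatten,
#' global average pooling and add contribute nothing.
#'
#' @param object an \linkS4class{ArchSpec}, \linkS4class{FloatModel} or
#'   \linkS4class{QuantizedModel}.
#' @return integer parameter total.
#' @examples
#' countParams(referenceArchitecture("mobilenet_1d"))  # 10738
#' @export
setGeneric("countParams", function(object) standardGeneric("countParams"))

#' Number of windows in a container
#' @param object a \linkS4class{WindowSet} or \linkS4class{SplitWindows}.
#' @return integer count (for SplitWindows, a named vector train/val/test).
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))

#' Records of a cohort
#' @param object a \linkS4class{PulseCohort}.
#' @return list of \linkS4class{BPRecord}.
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' Window values matrix (n x 1024)
#' @param object a \linkS4class{WindowSet}.
#' @return numeric matrix.
#' @export
setGeneric("windowValues", function(object) standardGeneric("windowValues"))

#' Window labels (sbp, dbp) in mmHg
#' @param object a \linkS4class{WindowSet}.
#' @return data.frame with columns sbp, dbp, recordId, startIndex.
#' @export
setGeneric("windowLabels", function(object) standardGeneric("windowLabels"))

#' @rdname nWindows
#' @export
setMethod("nWindows", "WindowSet", function(object) nrow(object@values))

#' @rdname nWindows
#' @export
setMethod("nWindows", "SplitWindows", function(object)
  c(train = nWindows(object@train), val = nWindows(object@val),
    test = nWindows(object@test)))

#' @rdname records
#' @export
setMethod("records", "PulseCohort", function(object) object@records)

#' @rdname windowValues
#' @export
setMethod("windowValues", "WindowSet", function(object) object@values)

#' @rdname windowLabels
#' @export
setMethod("windowLabels", "WindowSet", function(object)
  data.frame(sbp = object@sbp, dbp = object@dbp,
             recordId = object@recordId, startIndex = object@startIndex,
             stringsAsFactors = FALSE))

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nRecords, "records x",
      object@durationS, "s at 125 Hz\n")
  cat(sprintf("  SBP ~ truncNorm(%.2f, %.2f) on [%.2f, %.2f] mmHg\n",
              object@sbpMean, object@sbpSD, object@sbpMin, object@sbpMax))
  cat(sprintf("  DBP ~ %.0f + logNorm(%.3f, %.3f), truncated to [%.2f, %.2f] mmHg\n",
              object@dbpShift, object@dbpMeanlog, object@dbpSdlog,
              object@dbpMin, object@dbpMax))
  cat(sprintf("  noise SD %.3g, wander %.3g @ %.2f Hz, drift %.3g mmHg, seed %d\n",
              object@noiseSD, object@wanderAmplitude, object@wanderFreqHz,
              object@driftAmplitude, object@seed))
})

setMethod("show", "BPRecord", function(object) {
  cat(sprintf("BPRecord %s: %d samples (%.1f s) at %d Hz, %d annotated beats\n",
              object@recordId, length(object@ppg),
              length(object@ppg) / object@fs, object@fs,
              nrow(object@groundTruth)))
})

setMethod("show", "PulseCohort", function(object) {
  n <- length(object@records)
  cat("PulseCohort:", n, "records\n")
  if (n) {
    len <- vapply(object@records, function(r) length(r@ppg), integer(1))
    cat("  lengths:", min(len), "-", max(len), "samples\n")
  }
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows x 1024 samples\n", nWindows(object)))
  if (nWindows(object))
    cat(sprintf("  SBP %.1f-%.1f mmHg, DBP %.1f-%.1f mmHg, %d records\n",
                min(object@sbp), max(object@sbp), min(object@dbp),
                max(object@dbp), length(unique(object@recordId))))
})

setMethod("show", "SplitWindows", function(object) {
  n <- nWindows(object)
  cat(sprintf("SplitWindows: train %d / val %d / test %d windows\n",
              n["train"], n["val"], n["test"]))
  if (!is.null(object@config$nDeduplicated))
    cat("  duplicates removed from test:", object@config$nDeduplicated, "\n")
})

setMethod("show", "ArchSpec", function(object) {
  cat(sprintf("ArchSpec '%s': %d layers, %s trainable parameters\n",
              object@name, length(object@layers),
              format(countParams(object), big.mark = ",")))
})

setMethod("show", "FloatModel", function(object) {
  cat(sprintf("FloatModel '%s': %s parameters (float)\n",
              object@spec@name,
              format(countParams(object@spec), big.mark = ",")))
})

setMethod("show", "QuantizedModel", function(object) {
  cat(sprintf("QuantizedModel '%s': INT8 weights / INT32 biases, %d quantized edges\n",
              object@spec@name, length(object@edges)))
  cat(sprintf("  input scale %.4g (zp %d), output scale %.4g (zp %d)\n",
              object@inputQP$scale, object@inputQP$zeroPoint,
              object@outputQP$scale, object@outputQP$zeroPoint))
})

setMethod("show", "TrainResult", function(object) {
  cat(sprintf("TrainResult '%s': stopped at epoch %d, best epoch %d (val loss %.4f)\n",
              object@model@spec@name, object@stoppedEpoch, object@bestEpoch,
              object@history$valLoss[object@bestEpoch]))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat("BenchmarkReport:\n")
  cat("  float rows:", nrow(object@floatStats),
      " int8 rows:", nrow(object@int8Stats),
      " consistency rows:", nrow(object@consistency), "\n")
})
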