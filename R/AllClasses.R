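## Central S4 containers. Validity functions encode the structural invariants
## each downstream stage relies on.

#' CohortSpec: parameters of the synthetic PPG/ABP cohort generator
#'
#' Describes a synthetic cohort of paired PPG and arterial blood pressure
#' (ABP) records sampled at 125 Hz. Population systolic pressures follow a
#' truncated normal law on [78.25, 199.87] mmHg; diastolic pressures follow a
#' shifted log-normal truncated to [50.00, 158.02] mmHg (right-skewed), with
#' location parameters set so the medians land near 139.01 / 61.49 mmHg.
#'
#' @slot nRecords number of records to generate.
#' @slot durationS nominal record duration in seconds.
#' @slot sbpMean,sbpSD mean and SD of the (untruncated) systolic normal law,
#'   mmHg.
#' @slot sbpMin,sbpMax truncation support of the systolic law, mmHg.
#' @slot dbpShift,dbpMeanlog,dbpSdlog shift and log-scale parameters of the
#'   diastolic shifted log-normal law (dbp = shift + LogNormal(meanlog, sdlog)).
#' @slot dbpMin,dbpMax truncation support of the diastolic law, mmHg.
#' @slot heartRateBPM baseline heart rate, beats/min.
#' @slot noiseSD white-noise SD added to the PPG channel (normalized pulse
#'   units).
#' @slot wanderAmplitude,wanderFreqHz baseline-wander sinusoid amplitude
#'   (pulse units) and frequency (Hz), PPG channel only.
#' @slot driftAmplitude amplitude of the slow within-record SBP/DBP drift,
#'   mmHg.
#' @slot fractionShort fraction of records deliberately generated shorter than
#'   the 8-minute retention boundary (rounded to an exact count).
#' @slot fractionHighABP fraction of records deliberately generated with an
#'   ABP excursion above 200 mmHg (rounded to an exact count).
#' @slot seed RNG seed; identical specs generate bitwise-identical cohorts.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nRecords = "integer", durationS = "numeric",
    sbpMean = "numeric", sbpSD = "numeric",
    sbpMin = "numeric", sbpMax = "numeric",
    dbpShift = "numeric", dbpMeanlog = "numeric", dbpSdlog = "numeric",
    dbpMin = "numeric", dbpMax = "numeric",
    heartRateBPM = "numeric", noiseSD = "numeric",
    wanderAmplitude = "numeric", wanderFreqHz = "numeric",
    driftAmplitude = "numeric",
    fractionShort = "numeric", fractionHighABP = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nRecords < 1L) msg <- c(msg, "nRecords must be >= 1")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
  if (object@sbpMin >= object@sbpMax) msg <- c(msg, "invalid SBP support")
  if (object@dbpMin >= object@dbpMax) msg <- c(msg, "invalid DBP support")
  if (object@fractionShort < 0 || object@fractionHighABP < 0 ||
      object@fractionShort + object@fractionHighABP > 1)
    msg <- c(msg, "fractionShort + fractionHighABP must lie in [0, 1]")
  if (object@heartRateBPM < 40 || object@heartRateBPM > 180)
    msg <- c(msg, "heartRateBPM must lie in [40, 180]")
  if (object@noiseSD < 0 || object@wanderAmplitude < 0 ||
      object@driftAmplitude < 0)
    msg <- c(msg, "noise/wander/drift amplitudes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' BPRecord: one paired PPG + ABP record
#'
#' Aligned PPG and ABP sample series at 125 Hz. For synthetic records the
#' per-beat ground truth (peak/trough sample indices and attained SBP/DBP)
#' is carried along so window labels can be checked exactly.
#'
#' @slot recordId record identifier.
#' @slot fs sampling rate, Hz (always 125).
#' @slot ppg PPG samples, arbitrary units.
#' @slot abp ABP samples, mmHg.
#' @slot groundTruth data.frame with columns beat, peakIndex, troughIndex
#'   (1-based sample indices), sbp, dbp (mmHg); zero rows when unknown.
#' @exportClass BPRecord
setClass("BPRecord",
  representation(recordId = "character", fs = "integer",
                 ppg = "numeric", abp = "numeric",
                 groundTruth = "data.frame")
)

setValidity("BPRecord", function(object) {
  msg <- character()
  if (object@fs != 125L) msg <- c(msg, "fs must be 125 Hz")
  if (length(object@ppg) != length(object@abp))
    msg <- c(msg, "ppg and abp must be aligned (equal length)")
  if (length(msg)) msg else TRUE
})

#' PulseCohort: a list of BPRecords plus the spec that generated them
#' @slot records list of \linkS4class{BPRecord}.
#' @slot spec the \linkS4class{CohortSpec} used (may be a default stub for
#'   cohorts read from disk).
#' @exportClass PulseCohort
setClass("PulseCohort",
  representation(records = "list", spec = "CohortSpec"))

#' WindowSet: labeled 1024-sample PPG windows
#'
#' Each row of \code{values} is one 8.192 s window (1024 samples at 125 Hz) of
#' detrended, min-max normalized PPG; labels are the ABP maximum (SBP) and
#' minimum (DBP) over the same slice, in mmHg. Start indices are 0-based and
#' half-open: window i covers samples [start, start + 1024).
#'
#' @slot values numeric matrix, n x 1024, values in [0, 1].
#' @slot sbp,dbp numeric label vectors, mmHg.
#' @slot recordId character vector, provenance per window.
#' @slot startIndex integer vector, 0-based start sample (multiple of the hop).
#' @exportClass WindowSet
setClass("WindowSet",
  representation(values = "matrix", sbp = "numeric", dbp = "numeric",
                 recordId = "character", startIndex = "integer")
)

setValidity("WindowSet", function(object) {
  n <- nrow(object@values)
  msg <- character()
  if (n > 0L && ncol(object@values) < 1L)
    msg <- c(msg, "windows must have a positive sample width")
  if (length(object@sbp) != n || length(object@dbp) != n ||
      length(object@recordId) != n || length(object@startIndex) != n)
    msg <- c(msg, "label/provenance lengths must match the number of windows")
  if (n > 0L && any(object@dbp > object@sbp + 1e-9))
    msg <- c(msg, "dbp label must not exceed sbp label")
  if (length(msg)) msg else TRUE
})

#' SplitWindows: train/validation/test partition of a WindowSet
#' @slot train,val,test \linkS4class{WindowSet} partitions.
#' @slot config list recording fractions, seeds and dedup count.
#' @exportClass SplitWindows
setClass("SplitWindows",
  representation(train = "WindowSet", val = "WindowSet", test = "WindowSet",
                 config = "list"))

#' ArchSpec: declarative layer DAG of one architecture
#'
#' Layers form a DAG with a single source (the 1024 x 1 input) and a single
#' sink (the 2-element SBP/DBP regression output). Each layer is a list with
#' fields name, kind, and kind-specific fields (kernel, filters, stride,
#' dilation, padding, inputs).
#'
#' @slot name architecture name.
#' @slot layers ordered (topologically sorted) list of layer specs.
#' @slot declaredParams the frozen trainable-parameter total this
#'   configuration must reproduce.
#' @slot inputLength input window length (1024).
#' @exportClass ArchSpec
setClass("ArchSpec",
  representation(name = "character", layers = "list",
                 declaredParams = "integer", inputLength = "integer"))

setValidity("ArchSpec", function(object) {
  msg <- character()
  p <- tryCatch(countParams(object), error = function(e) NA_integer_)
  if (is.na(p)) msg <- c(msg, "parameter count is not computable (bad graph)")
  else if (length(object@declaredParams) == 1L &&
           !is.na(object@declaredParams) && p != object@declaredParams)
    msg <- c(msg, sprintf("parameter count %d != declared %d",
                          p, object@declaredParams))
  if (length(msg)) msg else TRUE
})

#' FloatModel: an ArchSpec plus float weights
#' @slot spec \linkS4class{ArchSpec}.
#' @slot weights named list (one entry per parametric layer) of lists with
#'   elements W and b.
#' @exportClass FloatModel
setClass("FloatModel",
  representation(spec = "ArchSpec", weights = "list"))

#' TrainConfig: training protocol settings
#' @slot optimizer "adam" or "adamw".
#' @slot learningRate initial learning rate.
#' @slot weightDecay decoupled weight decay (AdamW).
#' @slot loss "mse" or "huber".
#' @slot huberDelta Huber transition threshold (mmHg).
#' @slot batchSize minibatch size.
#' @slot maxEpochs epoch cap.
#' @slot earlyStopPatience epochs without validation improvement before
#'   stopping; NA disables early stopping.
#' @slot restoreBest restore the best-validation-loss weights at the end.
#' @slot plateauFactor,plateauPatience,minLR reduce-on-plateau schedule.
#' @slot seed RNG seed for init and shuffling.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(optimizer = "character", learningRate = "numeric",
                 weightDecay = "numeric", loss = "character",
                 huberDelta = "numeric", batchSize = "integer",
                 maxEpochs = "integer", earlyStopPatience = "integer",
                 restoreBest = "logical", plateauFactor = "numeric",
                 plateauPatience = "integer", minLR = "numeric",
                 seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@huberDelta <= 0) msg <- c(msg, "huberDelta must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (!object@optimizer %in% c("adam", "adamw"))
    msg <- c(msg, "optimizer must be adam or adamw")
  if (!object@loss %in% c("mse", "huber"))
    msg <- c(msg, "loss must be mse or huber")
  if (length(msg)) msg else TRUE
})

#' TrainResult: trained model plus training history
#' @slot model the returned \linkS4class{FloatModel} (best-validation weights
#'   when restoreBest).
#' @slot history data.frame with per-epoch train/val loss and learning rate.
#' @slot stoppedEpoch last epoch run.
#' @slot bestEpoch epoch whose validation loss was minimal.
#' @exportClass TrainResult
setClass("TrainResult",
  representation(model = "FloatModel", history = "data.frame",
                 stoppedEpoch = "integer", bestEpoch = "integer"))

#' CalibrationStats: per-activation-edge dynamic ranges
#' @slot ranges data.frame with columns edge, min, max.
#' @slot nSamples number of representative windows observed.
#' @exportClass CalibrationStats
setClass("CalibrationStats",
  representation(ranges = "data.frame", nSamples = "integer"))

setValidity("CalibrationStats", function(object) {
  if (nrow(object@ranges) &&
      any(object@ranges$min > object@ranges$max))
    "per-edge min must not exceed max" else TRUE
})

#' QuantizedModel: full-integer INT8 model
#'
#' Weights are per-channel symmetric INT8 (stored range [-127, 127]); biases
#' are INT32 at scale s_in * s_w per channel; activations are per-tensor
#' asymmetric INT8. Every requantization multiplier is precomputed as a 31-bit
#' mantissa and right shift at quantization time, so fixed-point inference
#' touches no floating-point value.
#'
#' @slot spec \linkS4class{ArchSpec}.
#' @slot layers named list of per-layer quantized tensors and requant
#'   parameters.
#' @slot edges named list of per-edge activation quantization parameters
#'   (scale, zeroPoint).
#' @slot inputQP,outputQP quantization parameters of the INT8 input and
#'   output tensors.
#' @exportClass QuantizedModel
setClass("QuantizedModel",
  representation(spec = "ArchSpec", layers = "list", edges = "list",
                 inputQP = "list", outputQP = "list"))

#' BenchmarkReport: results of one benchmark run
#' @slot floatStats data.frame of float ME/SD/MAE per model and target.
#' @slot int8Stats data.frame of INT8 ME/SD/MAE per model and target.
#' @slot drift data.frame of INT8-minus-float deltas with AAMI-style flags.
#' @slot consistency data.frame of FP32/INT8 Pearson correlations and max
#'   absolute prediction deltas per model.
#' @slot footprint data.frame of weight/activation byte footprints and duty
#'   cycle per model.
#' @slot meta list: seeds, config echo, window counts.
#' @exportClass BenchmarkReport
setClass("BenchmarkReport",
  representation(floatStats = "data.frame", int8Stats = "data.frame",
                 drift = "data.frame", consistency = "data.frame",
                 footprint = "data.frame", meta = "list"))
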