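## Benchmark orchestration: float comparison -> quantization robustness ->
## deployment feasibility arithmetic (weight/activation footprints, duty
## cycle). On-device latency is an input, never a measurement.

#' Inference-to-acquisition duty cycle
#'
#' 100 * latency_ms / (1000 * window_s): the fraction of each acquisition
#' window spent on inference. The study's example value, 165.8 ms per
#' 8.192 s window, gives about 2.0 percent.
#'
#' @param latencyMs inference latency per window, milliseconds (user input).
#' @param windowS acquisition window length, seconds.
#' @return list(percent = full precision, rounded = one decimal).
#' @examples
#' dutyCycle(165.8)$rounded  # 2.0
#' @export
dutyCycle <- function(latencyMs, windowS = 8.192) {
  stopifnot2(latencyMs >= 0, "latency must be non-negative")
  stopifnot2(windowS > 0, "window length must be positive")
  pct <- 100 * latencyMs / (1000 * windowS)
  list(percent = pct, rounded = round(pct, 1))
}

# documented serialization layout of the quantized weight payload:
# 1 byte per INT8 kernel element, 4 bytes per INT32 bias, plus a
# quantization-parameter table of 4 bytes per per-channel weight scale and
# 5 bytes (float32 scale + int8 zero point) per activation edge.
#' Quantized weight footprint in bytes
#'
#' @param qmodel a \linkS4class{QuantizedModel}.
#' @param detail return the per-component breakdown.
#' @return integer byte total (or list when \code{detail}).
#' @export
weightsBytes <- function(qmodel, detail = FALSE) {
  kern <- 0L; bias <- 0L; table <- 0L
  for (ql in qmodel@layers) {
    if (!is.null(ql$Wq)) {
      kern <- kern + length(ql$Wq)
      bias <- bias + 4L * length(ql$bq)
      table <- table + 4L * length(ql$wScale)
    }
  }
  table <- table + 5L * length(qmodel@edges)
  if (detail) list(kernel = kern, bias = bias, table = table,
                   total = kern + bias + table)
  else kern + bias + table
}

#' Peak activation buffer estimate in bytes
#'
#' Liveness analysis over the fixed topological schedule of the layer list:
#' each INT8 activation tensor (1 byte per element) is live from the step
#' that produces it until its last consumer; the peak is the maximum over
#' steps of the total bytes of simultaneously live tensors. This is a
#' documented scheduler of this package, not a reproduction of any vendor
#' toolchain's allocator.
#'
#' @param spec an \linkS4class{ArchSpec}.
#' @param inputLength input window length.
#' @return integer peak bytes.
#' @export
activationPeakBytes <- function(spec, inputLength = spec@inputLength) {
  shapes <- inferShapes(spec, inputLength)
  layerNames <- names(spec@layers)
  producedAt <- c(input = 0L,
                  stats::setNames(seq_along(layerNames), layerNames))
  lastUse <- stats::setNames(rep(0L, length(producedAt)),
                             names(producedAt))
  for (i in seq_along(spec@layers))
    for (nm in spec@layers[[i]]$inputs)
      lastUse[nm] <- max(lastUse[nm], i)
  # the sink is "used" at the final step
  lastUse[layerNames[length(layerNames)]] <- length(layerNames)
  sizes <- vapply(names(producedAt),
                  function(nm) prod(shapes[[nm]]), numeric(1))
  peak <- 0
  for (step in seq_along(layerNames)) {
    live <- names(producedAt)[producedAt <= step & lastUse >= step]
    peak <- max(peak, sum(sizes[live]))
  }
  as.integer(peak)
}

#' Run the structured two-stage benchmark
#'
#' Stage 1: generate the synthetic cohort, run the conditioning pipeline,
#' train every requested architecture and evaluate it in floating point on
#' the test split. Stage 2: quantize the selected architectures (calibrating
#' on representative training windows), evaluate the INT8 models on the same
#' test split, and report drift and FP32/INT8 consistency. Stage 3: report
#' footprint estimates and the duty cycle for a user-supplied latency.
#'
#' @param spec a \linkS4class{CohortSpec} describing the synthetic cohort.
#' @param architectures architecture names for stage 1.
#' @param quantized architecture names advanced to stage 2 (default: the
#'   two complementary design points, baseline and slim residual).
#' @param profile training profile ("fast" or "paper").
#' @param epochCap optional integer cap on training epochs (smoke tests and
#'   pipeline demonstrations; accuracy-bearing runs keep the profile
#'   defaults).
#' @param calibrationSize representative-set size (512).
#' @param latencyMs assumed on-device latency for the feasibility section.
#' @param minDurationS record retention threshold passed to the filter
#'   (desk-scale cohorts use shorter records than the 8-minute default).
#' @param splitSeed seed of the train/test partition.
#' @param outputDir optional directory for CSV/JSON artifacts.
#' @param verbose print stage progress.
#' @return a \linkS4class{BenchmarkReport}.
#' @export
runBenchmark <- function(spec = cohortSpec(),
                         architectures = c("baseline_cnn",
                                           "residual_cnn_slim"),
                         quantized = intersect(architectures,
                                               c("baseline_cnn",
                                                 "residual_cnn_slim")),
                         profile = "fast",
                         epochCap = NULL,
                         calibrationSize = 512L,
                         latencyMs = 165.8,
                         minDurationS = min(480, spec@durationS),
                         splitSeed = 42L,
                         outputDir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage 1: synthesizing cohort (%d records)", spec@nRecords)
  cohort <- generateCohort(spec)
  windows <- preprocessCohort(cohort, minDurationS = minDurationS)
  stopifnot2(nWindows(windows) >= 10L,
             "stage preprocess failed: too few windows survive filtering")
  splits <- assembleSplits(windows, splitSeed = splitSeed)
  say("  %d windows: train %d / val %d / test %d", nWindows(windows),
      nWindows(splits@train), nWindows(splits@val), nWindows(splits@test))
  stopifnot2(calibrationSize <= nWindows(splits@train),
             "calibration size exceeds the training set")

  testX <- windowValues(splits@test)
  sbpRef <- splits@test@sbp; dbpRef <- splits@test@dbp
  floatStats <- list(); int8Stats <- list(); driftRows <- list()
  consRows <- list(); footRows <- list()
  trained <- list(); quantizedModels <- list()

  for (arch in architectures) {
    say("stage 1: training %s", arch)
    aspec <- referenceArchitecture(arch)
    cfg <- defaultTrainConfig(arch, profile = profile)
    if (!is.null(epochCap))
      cfg@maxEpochs <- min(cfg@maxEpochs, as.integer(epochCap))
    res <- trainModel(aspec, splits, cfg)
    trained[[arch]] <- res
    pred <- forwardFloat(res@model, testX)
    st <- predictionStats(pred, sbpRef, dbpRef)
    st <- cbind(model = arch, precision = "float", st,
                params = countParams(aspec))
    floatStats[[arch]] <- st
  }

  for (arch in quantized) {
    say("stage 2: quantizing %s", arch)
    res <- trained[[arch]]
    rep_idx <- withSeed(splitSeed + 1L,
                        sample.int(nWindows(splits@train),
                                   min(calibrationSize,
                                       nWindows(splits@train))))
    stats <- calibrate(res@model,
                       windowValues(splits@train)[rep_idx, , drop = FALSE])
    qm <- quantizeModel(res@model, stats)
    quantizedModels[[arch]] <- qm
    fpPred <- forwardFloat(res@model, testX)
    qPred <- forwardInt8(qm, testX)$pred
    stI <- predictionStats(qPred, sbpRef, dbpRef)
    int8Stats[[arch]] <- cbind(model = arch, precision = "int8", stI,
                               params = countParams(qm))
    fpStats <- predictionStats(fpPred, sbpRef, dbpRef)
    dr <- driftReport(fpStats, stI, fpPred, qPred)
    driftRows[[arch]] <- cbind(model = arch, dr$drift)
    consRows[[arch]] <- cbind(
      model = arch, dr$consistency,
      violations = physiologicalCheck(qPred))
    dc <- dutyCycle(latencyMs)
    footRows[[arch]] <- data.frame(
      model = arch,
      weightsBytes = weightsBytes(qm),
      activationPeakBytes = activationPeakBytes(qm@spec),
      latencyMs = latencyMs,
      dutyCyclePct = dc$rounded)
  }

  report <- new("BenchmarkReport",
    floatStats = do.call(rbind, floatStats),
    int8Stats = if (length(int8Stats)) do.call(rbind, int8Stats)
                else data.frame(),
    drift = if (length(driftRows)) do.call(rbind, driftRows)
            else data.frame(),
    consistency = if (length(consRows)) do.call(rbind, consRows)
                  else data.frame(),
    footprint = if (length(footRows)) do.call(rbind, footRows)
                else data.frame(),
    meta = list(spec = spec, splitSeed = splitSeed, profile = profile,
                nWindows = nWindows(windows),
                splitSizes = nWindows(splits),
                calibrationSize = calibrationSize,
                timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (!is.null(outputDir)) writeBenchmarkReport(report, outputDir)
  report
}

#' Write a benchmark report to disk
#'
#' CSV tables (float/int8 statistics, drift, consistency, footprint) plus a
#' JSON manifest with the seeds and configuration echo.
#'
#' @param report a \linkS4class{BenchmarkReport}.
#' @param dir output directory (created if needed).
#' @return dir, invisibly.
#' @export
writeBenchmarkReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm)
    if (nrow(df)) write.csv(df, file.path(dir, nm), row.names = FALSE)
  wr(report@floatStats, "float_stats.csv")
  wr(report@int8Stats, "int8_stats.csv")
  wr(report@drift, "drift.csv")
  wr(report@consistency, "consistency.csv")
  wr(report@footprint, "footprint.csv")
  meta <- report@meta
  meta$spec <- NULL
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
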