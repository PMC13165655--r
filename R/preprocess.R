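## Signal conditioning pipeline: record filtering, detrending, min-max
## normalization, overlapping windowing with SBP/DBP labeling, and the
## split/deduplication protocol.

#' Filter records by validity rules
#'
#' A record is kept iff it is at least \code{minDurationS} long (the default
#' 480 s corresponds to the 8-minute retention boundary, 60,000 samples at
#' 125 Hz), its ABP never exceeds \code{maxABP} (peaks strictly above
#' 200 mmHg are excluded), and both channels are finite and non-constant.
#'
#' @param x a \linkS4class{PulseCohort} or list of \linkS4class{BPRecord}.
#' @param maxABP exclusion threshold for ABP peaks, mmHg.
#' @param minDurationS minimum retained duration, seconds. Desk-scale
#'   benchmark configurations may lower this to run the full pipeline on
#'   shorter synthetic records.
#' @return list with elements \code{kept} (list of records) and
#'   \code{rejected} (data.frame recordId, reason).
#' @export
selectRecords <- function(x, maxABP = 200, minDurationS = 480) {
  recs <- if (is(x, "PulseCohort")) records(x) else x
  minN <- round(minDurationS * 125)
  kept <- list(); rej <- list()
  for (r in recs) {
    reason <- NULL
    if (length(r@ppg) < minN) reason <- "too_short"
    else if (!all(is.finite(r@ppg)) || !all(is.finite(r@abp)))
      reason <- "nonfinite_channel"
    else if (max(r@ppg) == min(r@ppg) || max(r@abp) == min(r@abp))
      reason <- "constant_channel"
    else if (max(r@abp) > maxABP) reason <- "abp_peak_above_threshold"
    if (is.null(reason)) kept[[length(kept) + 1L]] <- r
    else rej[[length(rej) + 1L]] <- data.frame(recordId = r@recordId,
                                               reason = reason)
  }
  list(kept = kept,
       rejected = if (length(rej)) do.call(rbind, rej)
                  else data.frame(recordId = character(),
                                  reason = character()))
}

#' Remove baseline trend from a PPG series
#'
#' The default removes the per-record least-squares line a + b*t (the
#' conventional meaning of detrending). A moving-average high-pass is
#' available as an alternative: the centred running mean over
#' \code{windowS} seconds is subtracted instead.
#'
#' @param ppg numeric series, at least 2 finite samples, non-constant.
#' @param method "linear" (default) or "moving_average".
#' @param windowS moving-average window, seconds (method
#'   "moving_average").
#' @param fs sampling rate, Hz.
#' @return detrended series of the same length.
#' @examples
#' x <- 3 + 0.5 * (1:100) + sin(1:100 / 5)
#' max(abs(detrendPPG(x) - detrendPPG(sin(1:100 / 5)))) < 1e-9
#' @export
detrendPPG <- function(ppg, method = c("linear", "moving_average"),
                       windowS = 2, fs = 125L) {
  method <- match.arg(method)
  n <- length(ppg)
  stopifnot2(n >= 2L, "detrending needs at least 2 samples")
  stopifnot2(all(is.finite(ppg)), "detrending needs finite samples")
  stopifnot2(max(ppg) > min(ppg), "constant signal cannot be detrended")
  if (method == "linear") {
    t <- seq_len(n) - (n + 1) / 2        # centred time axis
    b <- sum(t * ppg) / sum(t * t)
    return(ppg - mean(ppg) - b * t)
  }
  k <- min(n, max(3L, as.integer(round(windowS * fs)) %/% 2L * 2L + 1L))
  ma <- as.numeric(stats::filter(ppg, rep(1 / k, k), sides = 2))
  # running mean is undefined at the edges; extend with the nearest value
  ma <- approx(which(!is.na(ma)), ma[!is.na(ma)], xout = seq_len(n),
               rule = 2)$y
  ppg - ma
}

#' Min-max normalize to [0, 1]
#'
#' @param ppg numeric series with \code{max > min}.
#' @return \code{(x - min) / (max - min)}.
#' @export
normalizeMinMax <- function(ppg) {
  rng <- range(ppg)
  stopifnot2(is.finite(rng[1]) && is.finite(rng[2]),
             "non-finite samples cannot be normalized")
  stopifnot2(rng[2] > rng[1], "constant signal cannot be min-max normalized")
  (ppg - rng[1]) / (rng[2] - rng[1])
}

# condition one record: detrend + normalize the PPG channel (per record)
conditionRecord <- function(record) {
  record@ppg <- normalizeMinMax(detrendPPG(record@ppg))
  record
}

#' Segment a conditioned record into labeled windows
#'
#' Cuts 8.192 s windows (1024 samples at 125 Hz) with 75% overlap
#' (hop = 256): start indices 0, 256, 512, ... while
#' \code{start + 1024 <= N}, giving \code{floor((N - 1024)/256) + 1} windows.
#' Each window is labeled with the ABP maximum (SBP) and minimum (DBP) over
#' the same half-open slice.
#'
#' @param record a \linkS4class{BPRecord} whose PPG is already detrended and
#'   min-max normalized.
#' @param windowLen window length, samples.
#' @param hop hop between starts, samples (256 = 25% of 1024).
#' @return a \linkS4class{WindowSet} (empty, with a message, when the record
#'   is shorter than one window).
#' @export
segmentRecord <- function(record, windowLen = 1024L, hop = 256L) {
  n <- length(record@ppg)
  if (n < windowLen) {
    message(sprintf("record %s shorter than one window (%d < %d); skipped",
                    record@recordId, n, windowLen))
    return(new("WindowSet",
               values = matrix(numeric(0), 0L, windowLen),
               sbp = numeric(0), dbp = numeric(0),
               recordId = character(0), startIndex = integer(0)))
  }
  starts <- seq.int(0L, n - windowLen, by = hop)
  vals <- matrix(0, length(starts), windowLen)
  sbp <- numeric(length(starts)); dbp <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):(starts[i] + windowLen)
    vals[i, ] <- record@ppg[idx]
    sbp[i] <- max(record@abp[idx])
    dbp[i] <- min(record@abp[idx])
  }
  new("WindowSet", values = vals, sbp = sbp, dbp = dbp,
      recordId = rep(record@recordId, length(starts)),
      startIndex = as.integer(starts))
}

# row-bind WindowSets
bindWindowSets <- function(sets) {
  sets <- Filter(function(s) nWindows(s) > 0L, sets)
  if (!length(sets))
    return(new("WindowSet", values = matrix(numeric(0), 0L, 1024L),
               sbp = numeric(0), dbp = numeric(0),
               recordId = character(0), startIndex = integer(0)))
  new("WindowSet",
      values = do.call(rbind, lapply(sets, function(s) s@values)),
      sbp = unlist(lapply(sets, function(s) s@sbp), use.names = FALSE),
      dbp = unlist(lapply(sets, function(s) s@dbp), use.names = FALSE),
      recordId = unlist(lapply(sets, function(s) s@recordId),
                        use.names = FALSE),
      startIndex = unlist(lapply(sets, function(s) s@startIndex),
                          use.names = FALSE))
}

# subset a WindowSet by row index
subsetWindows <- function(ws, idx) {
  new("WindowSet", values = ws@values[idx, , drop = FALSE],
      sbp = ws@sbp[idx], dbp = ws@dbp[idx],
      recordId = ws@recordId[idx], startIndex = ws@startIndex[idx])
}

#' Run the full conditioning pipeline on a cohort
#'
#' Filters records, detrends and min-max normalizes each surviving PPG
#' channel per record, and segments everything into one labeled
#' \linkS4class{WindowSet}.
#'
#' @param cohort a \linkS4class{PulseCohort} (or list of records).
#' @param maxABP,minDurationS filtering rules, see
#'   \code{\link{selectRecords}}.
#' @return a \linkS4class{WindowSet}.
#' @export
preprocessCohort <- function(cohort, maxABP = 200, minDurationS = 480) {
  sel <- selectRecords(cohort, maxABP = maxABP, minDurationS = minDurationS)
  bindWindowSets(lapply(sel$kept,
                        function(r) segmentRecord(conditionRecord(r))))
}

# exact-identity row keys (hex float rendering, bit-faithful)
windowKeys <- function(values) {
  hx <- sprintf("%a", values)
  dim(hx) <- dim(values)
  do.call(paste, c(as.data.frame(hx, stringsAsFactors = FALSE), sep = " "))
}

#' Partition windows into train/validation/test with deduplication
#'
#' Window-level random 70/30 train/test partition (the deliberately
#' leakage-prone protocol of the window-level evaluation; subject-wise
#' splitting is available via \code{subjectWise = TRUE}). Test windows whose
#' normalized value vectors are exactly identical to a training-pool window
#' are removed from the test side. The remaining training pool is then
#' shuffled and split 80/20 into train/validation with its own fixed seed.
#' Sizes follow nearest-integer rounding with ties up.
#'
#' @param windows a \linkS4class{WindowSet} (>= 10 windows).
#' @param testFraction fraction of windows assigned to test.
#' @param valFraction fraction of the training pool assigned to validation.
#' @param splitSeed seed of the train/test partition.
#' @param valSeed seed of the train/validation shuffle (fixed default 42).
#' @param subjectWise if TRUE, the test partition is drawn at the record
#'   level instead (no window of a test record appears in training).
#' @return a \linkS4class{SplitWindows}.
#' @export
assembleSplits <- function(windows, testFraction = 0.30, valFraction = 0.20,
                           splitSeed = 42L, valSeed = 42L,
                           subjectWise = FALSE) {
  n <- nWindows(windows)
  stopifnot2(n >= 10L, "need at least 10 windows to split")
  stopifnot2(testFraction > 0 && testFraction < 1 &&
             valFraction > 0 && valFraction < 1,
             "fractions must lie in (0, 1)")
  testIdx <- withSeed(splitSeed, {
    if (subjectWise) {
      ids <- unique(windows@recordId)
      nTestRec <- max(1L, roundHalfUp(length(ids) * testFraction))
      testIds <- sample(ids, nTestRec)
      which(windows@recordId %in% testIds)
    } else {
      nTest <- roundHalfUp(n * testFraction)
      sort(sample.int(n, nTest))
    }
  })
  poolIdx <- setdiff(seq_len(n), testIdx)

  keys <- windowKeys(windows@values)
  dup <- keys[testIdx] %in% keys[poolIdx]
  testIdx <- testIdx[!dup]

  valTrain <- withSeed(valSeed, {
    shuffled <- sample(poolIdx)
    nVal <- roundHalfUp(length(poolIdx) * valFraction)
    list(val = shuffled[seq_len(nVal)],
         train = shuffled[-seq_len(nVal)])
  })
  new("SplitWindows",
      train = subsetWindows(windows, valTrain$train),
      val = subsetWindows(windows, valTrain$val),
      test = subsetWindows(windows, testIdx),
      config = list(testFraction = testFraction, valFraction = valFraction,
                    splitSeed = splitSeed, valSeed = valSeed,
                    subjectWise = subjectWise,
                    nDeduplicated = sum(dup)))
}
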