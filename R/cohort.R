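## Synthetic paired PPG/ABP cohort generation.
##
## The generator exists to exercise the full pipeline with known per-beat
## ground truth: each arterial beat is an additive two-lobe pressure shape
## (systolic lobe + dicrotic lobe) rescaled per beat so its sampled minimum
## and maximum equal the diastolic and systolic targets EXACTLY; window
## labels computed downstream are therefore checkable against construction.
## The PPG channel is a low-pass filtered, lag-shifted, amplitude-normalized
## copy of the pulse shape with baseline wander and white noise added (ABP is
## left noise-free so labels stay exact).

# run expr with a local RNG seeded at `seed`, restoring the caller's RNG
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a synthetic cohort specification
#'
#' Defaults describe the desk-scale study cohort: 100 records of 2 minutes at
#' 125 Hz. Systolic targets are drawn from a truncated normal on
#' [78.25, 199.87] mmHg centred at 139.01; diastolic targets from a shifted
#' log-normal (right-skewed) truncated to [50.00, 158.02] mmHg whose median
#' sits at 61.49 when \code{dbpMeanlog = log(61.49 - 50)}.
#'
#' @param nRecords number of records.
#' @param durationS record duration, seconds.
#' @param sbpMean,sbpSD location/scale of the systolic normal law, mmHg.
#' @param sbpMin,sbpMax systolic truncation support, mmHg.
#' @param dbpShift,dbpMeanlog,dbpSdlog diastolic shifted log-normal
#'   parameters (dbp = dbpShift + LogNormal(dbpMeanlog, dbpSdlog)).
#' @param dbpMin,dbpMax diastolic truncation support, mmHg.
#' @param heartRateBPM baseline heart rate, beats/min.
#' @param noiseSD PPG white-noise SD (normalized pulse units).
#' @param wanderAmplitude,wanderFreqHz PPG baseline-wander sinusoid.
#' @param driftAmplitude slow within-record SBP drift amplitude, mmHg (DBP
#'   drifts at half this amplitude).
#' @param fractionShort,fractionHighABP fractions of deliberately invalid
#'   records (shorter than 8 minutes / containing an ABP excursion above
#'   200 mmHg); converted to exact counts by rounding.
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{CohortSpec}.
#' @examples
#' spec <- cohortSpec(nRecords = 5L, durationS = 30)
#' spec
#' @export
cohortSpec <- function(nRecords = 100L, durationS = 120,
                       sbpMean = 139.01, sbpSD = 24,
                       sbpMin = 78.25, sbpMax = 199.87,
                       dbpShift = 50, dbpMeanlog = log(61.49 - 50),
                       dbpSdlog = 0.55,
                       dbpMin = 50.00, dbpMax = 158.02,
                       heartRateBPM = 75, noiseSD = 0.03,
                       wanderAmplitude = 0.25, wanderFreqHz = 0.25,
                       driftAmplitude = 8,
                       fractionShort = 0, fractionHighABP = 0,
                       seed = 42L) {
  new("CohortSpec", nRecords = as.integer(nRecords), durationS = durationS,
      sbpMean = sbpMean, sbpSD = sbpSD, sbpMin = sbpMin, sbpMax = sbpMax,
      dbpShift = dbpShift, dbpMeanlog = dbpMeanlog, dbpSdlog = dbpSdlog,
      dbpMin = dbpMin, dbpMax = dbpMax,
      heartRateBPM = heartRateBPM, noiseSD = noiseSD,
      wanderAmplitude = wanderAmplitude, wanderFreqHz = wanderFreqHz,
      driftAmplitude = driftAmplitude,
      fractionShort = fractionShort, fractionHighABP = fractionHighABP,
      seed = as.integer(seed))
}

#' Sample population SBP/DBP targets
#'
#' Draws one (SBP, DBP) pair per record by rejection: SBP from the truncated
#' normal, DBP from the truncated shifted log-normal, resampling DBP until
#' \code{dbp <= sbp - 10} (a minimum physiological pulse pressure). With the
#' default laws the empirical medians land near 139.01 / 61.49 mmHg and the
#' DBP sample is right-skewed.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param n number of pairs (defaults to \code{nRecords}).
#' @param maxIter rejection-loop cap per draw; exceeding it signals an
#'   invalid spec.
#' @return data.frame with columns sbp, dbp (mmHg).
#' @export
samplePopulationTargets <- function(spec, n = spec@nRecords,
                                    maxIter = 1000L) {
  validObject(spec)
  drawSBP <- function(m) {
    out <- numeric(0)
    it <- 0L
    while (length(out) < m) {
      it <- it + 1L
      if (it > maxIter)
        stop("rejection sampling failed: SBP law incompatible with support")
      x <- rnorm(m, spec@sbpMean, spec@sbpSD)
      out <- c(out, x[x >= spec@sbpMin & x <= spec@sbpMax])
    }
    out[seq_len(m)]
  }
  drawDBP <- function(m) {
    out <- numeric(0)
    it <- 0L
    while (length(out) < m) {
      it <- it + 1L
      if (it > maxIter)
        stop("rejection sampling failed: DBP law incompatible with support")
      x <- spec@dbpShift + rlnorm(m, spec@dbpMeanlog, spec@dbpSdlog)
      out <- c(out, x[x >= spec@dbpMin & x <= spec@dbpMax])
    }
    out[seq_len(m)]
  }
  sbp <- drawSBP(n)
  dbp <- drawDBP(n)
  bad <- which(dbp > sbp - 10)
  it <- 0L
  while (length(bad)) {
    it <- it + 1L
    if (it > maxIter)
      stop("rejection sampling failed: cannot satisfy dbp <= sbp - 10 ",
           "(spec invalid)")
    dbp[bad] <- drawDBP(length(bad))
    bad <- bad[dbp[bad] > sbp[bad] - 10]
  }
  data.frame(sbp = sbp, dbp = dbp)
}

#' Construct per-beat synthesis parameters
#'
#' @param heartRateBPM beat rate, beats/min, in [40, 180].
#' @param sbpTarget,dbpTarget systolic/diastolic targets, mmHg
#'   (\code{dbpTarget < sbpTarget}).
#' @param systolicWidth width of the systolic lobe, seconds.
#' @param dicroticAmplitude dicrotic lobe amplitude as a fraction of pulse
#'   pressure, in [0, 0.5].
#' @param dicroticDelay delay of the dicrotic lobe after the systolic peak,
#'   seconds (shorter than one beat period).
#' @param ppgLag PPG lag behind ABP, samples (>= 0).
#' @param lowpassCutoff PPG low-pass cutoff, Hz.
#' @return validated list of beat parameters.
#' @export
beatParams <- function(heartRateBPM = 75, sbpTarget = 120, dbpTarget = 80,
                       systolicWidth = 0.12, dicroticAmplitude = 0.25,
                       dicroticDelay = 0.25, ppgLag = 25L,
                       lowpassCutoff = 8) {
  period <- 60 / heartRateBPM
  vals <- c(heartRateBPM, sbpTarget, dbpTarget, systolicWidth,
            dicroticAmplitude, dicroticDelay, lowpassCutoff)
  stopifnot2(all(is.finite(vals)), "beat parameters must be finite")
  stopifnot2(dbpTarget < sbpTarget, "dbpTarget must be below sbpTarget")
  stopifnot2(heartRateBPM >= 40 && heartRateBPM <= 180,
             "heartRateBPM must lie in [40, 180]")
  stopifnot2(systolicWidth > 0 && systolicWidth < period,
             "systolicWidth must be positive and shorter than one beat")
  stopifnot2(dicroticDelay > 0 && dicroticDelay < period,
             "dicroticDelay must be positive and shorter than one beat")
  stopifnot2(dicroticAmplitude >= 0 && dicroticAmplitude <= 0.5,
             "dicroticAmplitude must lie in [0, 0.5]")
  stopifnot2(ppgLag >= 0, "ppgLag must be >= 0")
  list(heartRateBPM = heartRateBPM, sbpTarget = sbpTarget,
       dbpTarget = dbpTarget, systolicWidth = systolicWidth,
       dicroticAmplitude = dicroticAmplitude, dicroticDelay = dicroticDelay,
       ppgLag = as.integer(ppgLag), lowpassCutoff = lowpassCutoff)
}

# raw (unscaled) two-lobe beat shape on n samples at fs;
# systolic Gaussian lobe at 30% of the period + dicrotic lobe after it
beatShapeRaw <- function(params, n, fs = 125L) {
  period <- n / fs
  t <- (seq_len(n) - 1) / fs
  tPeak <- 0.3 * period
  w <- params$systolicWidth
  g <- exp(-0.5 * ((t - tPeak) / w)^2) +
    params$dicroticAmplitude *
      exp(-0.5 * ((t - tPeak - params$dicroticDelay) / (1.5 * w))^2)
  g
}

#' Synthesize one arterial beat and its PPG counterpart
#'
#' The ABP beat is \code{dbp + (sbp - dbp) * g(t)} where g is a two-lobe
#' (systolic + dicrotic) shape rescaled over its sampled values so that
#' \code{min(g) = 0} and \code{max(g) = 1}; the beat therefore attains its
#' diastolic and systolic targets exactly. The PPG beat is a second-order
#' Butterworth low-pass filtered, lag-shifted, min-max normalized copy of
#' the pulse shape.
#'
#' @param params a \code{\link{beatParams}} list.
#' @param fs sampling rate, Hz.
#' @return list with elements \code{abp} (mmHg) and \code{ppg} (normalized),
#'   both of length \code{round(fs * 60 / heartRateBPM)}.
#' @examples
#' b <- synthesizeBeat(beatParams(sbpTarget = 120, dbpTarget = 80))
#' range(b$abp)  # exactly 80 120
#' @export
synthesizeBeat <- function(params, fs = 125L) {
  n <- max(8L, as.integer(round(fs * 60 / params$heartRateBPM)))
  g <- beatShapeRaw(params, n, fs)
  g <- (g - min(g)) / (max(g) - min(g))
  abp <- params$dbpTarget + (params$sbpTarget - params$dbpTarget) * g
  bf <- signal::butter(2, min(0.99, params$lowpassCutoff / (fs / 2)),
                       type = "low")
  ppg <- as.numeric(signal::filtfilt(bf, g))
  lag <- min(params$ppgLag, n - 1L)
  if (lag > 0) ppg <- c(ppg[(n - lag + 1L):n], ppg[1:(n - lag)])
  rng <- range(ppg)
  if (rng[2] > rng[1]) ppg <- (ppg - rng[1]) / (rng[2] - rng[1])
  list(abp = abp, ppg = ppg)
}

#' Generate one synthetic record
#'
#' Beats are concatenated with beat-to-beat heart-rate jitter and a slow
#' sinusoidal SBP/DBP drift around the record targets; baseline wander and
#' white noise are added to the PPG channel only, so each beat's ABP extrema
#' equal the recorded ground truth exactly. The record is truncated to
#' exactly \code{round(durationS * 125)} samples.
#'
#' @param spec a \linkS4class{CohortSpec} (noise and drift settings are
#'   taken from it).
#' @param targets numeric c(sbp, dbp) record-level targets, mmHg.
#' @param durationS record duration, seconds.
#' @param recordId identifier.
#' @param highABP if TRUE one mid-record beat is driven above 200 mmHg (to
#'   exercise the exclusion filter).
#' @return a \linkS4class{BPRecord} with populated per-beat ground truth.
#' @export
generateRecord <- function(spec, targets, durationS = spec@durationS,
                           recordId = "rec", highABP = FALSE) {
  stopifnot2(durationS > 0, "durationS must be positive")
  fs <- 125L
  nTotal <- as.integer(round(durationS * fs))
  sbp0 <- targets[[1]]; dbp0 <- targets[[2]]

  abp <- numeric(0); pulse <- numeric(0)
  gt <- list()
  beat <- 0L
  # pressure-dependent morphology: the PPG must encode the targets for a
  # supervised task to exist. Pulse amplitude scales with pulse pressure
  # (read against the fixed wander amplitude, which survives per-record
  # min-max normalization); the systolic lobe widens with SBP; the dicrotic
  # lobe shrinks with DBP.
  morph <- function(sbp, dbp)
    list(width = min(0.95 * 60 / 180, 0.09 + 0.00035 * (sbp - 78)),
         dicro = min(0.5, max(0.05, 0.5 - 0.004 * (dbp - 50))),
         amp = 0.4 + 0.6 * (sbp - dbp) / 150)
  # rough beat count to place the high-ABP excursion mid-record
  approxBeats <- max(1, floor(durationS * spec@heartRateBPM / 60))
  spikeBeat <- if (highABP) max(1L, as.integer(approxBeats %/% 2L)) else -1L
  while (length(abp) < nTotal) {
    beat <- beat + 1L
    hr <- min(180, max(40, spec@heartRateBPM * (1 + 0.03 * rnorm(1))))
    tBeat <- length(abp) / fs
    drift <- sin(2 * pi * tBeat / 60)
    sbpB <- sbp0 + spec@driftAmplitude * drift
    dbpB <- dbp0 + 0.5 * spec@driftAmplitude * drift
    if (beat == spikeBeat) sbpB <- max(210, sbpB + 30)
    if (dbpB > sbpB - 10) dbpB <- sbpB - 10
    mo <- morph(sbpB, dbpB)
    p <- beatParams(heartRateBPM = hr, sbpTarget = sbpB, dbpTarget = dbpB,
                    systolicWidth = mo$width, dicroticAmplitude = mo$dicro)
    b <- synthesizeBeat(p, fs)
    offset <- length(abp)
    abp <- c(abp, b$abp)
    pulse <- c(pulse, mo$amp * b$ppg)
    gt[[beat]] <- data.frame(
      beat = beat,
      peakIndex = offset + which.max(b$abp),
      troughIndex = offset + which.min(b$abp),
      sbp = max(b$abp), dbp = min(b$abp))
  }
  abp <- abp[seq_len(nTotal)]
  pulse <- pulse[seq_len(nTotal)]
  gtDF <- do.call(rbind, gt)
  # drop beats whose extrema were cut off by truncation
  gtDF <- gtDF[gtDF$peakIndex <= nTotal & gtDF$troughIndex <= nTotal, ,
               drop = FALSE]

  t <- (seq_len(nTotal) - 1) / fs
  ppg <- pulse +
    spec@wanderAmplitude * sin(2 * pi * spec@wanderFreqHz * t) +
    if (spec@noiseSD > 0) rnorm(nTotal, 0, spec@noiseSD) else 0
  new("BPRecord", recordId = recordId, fs = fs, ppg = ppg, abp = abp,
      groundTruth = gtDF)
}

#' Generate a synthetic cohort
#'
#' Draws per-record SBP/DBP targets, then generates records. Deliberately
#' invalid records are injected in deterministic counts:
#' \code{round(fractionShort * nRecords)} records are generated at half
#' duration (always below the 60,000-sample retention boundary) and
#' \code{round(fractionHighABP * nRecords)} records contain one ABP
#' excursion above 200 mmHg. Identical (spec, seed) yield bitwise-identical
#' cohorts.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return a \linkS4class{PulseCohort}.
#' @examples
#' coh <- generateCohort(cohortSpec(nRecords = 3L, durationS = 20))
#' coh
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nRecords
  nShort <- as.integer(roundHalfUp(spec@fractionShort * n))
  nHigh <- as.integer(roundHalfUp(spec@fractionHighABP * n))
  stopifnot2(nShort + nHigh <= n,
             "fractionShort + fractionHighABP exceed the cohort")
  withSeed(spec@seed, {
    targets <- samplePopulationTargets(spec, n)
    shortDur <- min(spec@durationS, 480) / 2
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      isShort <- i <= nShort
      isHigh <- !isShort && i <= nShort + nHigh
      recs[[i]] <- generateRecord(
        spec, c(targets$sbp[i], targets$dbp[i]),
        durationS = if (isShort) shortDur else spec@durationS,
        recordId = sprintf("synth-%04d", i),
        highABP = isHigh)
    }
    new("PulseCohort", records = recs, spec = spec)
  })
}
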