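# Conditioning pipeline: filtering boundaries, detrending, normalization,
# windowing arithmetic and the split/dedup protocol.

test_that("record filter boundaries are exact", {
  r59999 <- sineRecord(59999L, "a")
  r60000 <- sineRecord(60000L, "b")
  sel <- selectRecords(list(r59999, r60000))
  expect_identical(length(sel$kept), 1L)
  expect_identical(sel$kept[[1]]@recordId, "b")
  expect_identical(sel$rejected$reason, "too_short")

  atLimit <- sineRecord(60000L, "limit", abpMax = 200.0)
  above <- sineRecord(60000L, "above", abpMax = 200.01)
  sel2 <- selectRecords(list(atLimit, above))
  expect_identical(length(sel2$kept), 1L)
  expect_identical(sel2$kept[[1]]@recordId, "limit")
  expect_identical(sel2$rejected$reason, "abp_peak_above_threshold")

  flat <- sineRecord(60000L, "flat")
  flat@ppg <- rep(1, 60000L)
  sel3 <- selectRecords(list(flat))
  expect_identical(sel3$rejected$reason, "constant_channel")

  expect_identical(length(selectRecords(list())$kept), 0L)
})

test_that("linear detrending removes exactly the least-squares line", {
  t <- 1:500
  expect_lt(max(abs(detrendPPG(3 + 0.02 * t))), 1e-9)
  # sinusoid orthogonal to the line on this grid (even about the midpoint,
  # whole number of periods): detrending must leave it untouched
  s <- cos(2 * pi * (t - 250.5) / 50)
  expect_lt(max(abs(detrendPPG(s) - s)), 1e-9)
  s2 <- sin(2 * pi * t / 50)
  # direct normal-equations oracle on sinusoid + ramp
  x <- s2 + 0.01 * t
  fit <- lm(x ~ t)
  expect_equal(detrendPPG(x), unname(residuals(fit)), tolerance = 1e-9)
  expect_error(detrendPPG(rep(2, 10)), "constant")
  expect_error(detrendPPG(1), "at least 2")
})

test_that("min-max normalization maps endpoints to 0 and 1", {
  expect_equal(normalizeMinMax(c(-1, 0, 1)), c(0, 0.5, 1))
  u <- runif(100)
  nm <- normalizeMinMax(u)
  expect_identical(min(nm), 0)
  expect_identical(max(nm), 1)
  v <- c(0, runif(50), 1)
  expect_identical(normalizeMinMax(v), v)   # attains both endpoints
  expect_error(normalizeMinMax(rep(0.5, 4)), "constant")
})

test_that("window segmentation counts and labels follow the arithmetic", {
  r1 <- sineRecord(1024L)
  w1 <- segmentRecord(edgeBP:::conditionRecord(r1))
  expect_identical(nWindows(w1), 1L)
  expect_identical(w1@startIndex, 0L)

  r2 <- sineRecord(2048L)
  w2 <- segmentRecord(edgeBP:::conditionRecord(r2))
  expect_identical(nWindows(w2), 5L)
  expect_identical(w2@startIndex, c(0L, 256L, 512L, 768L, 1024L))

  # 8.192 s windows at 125 Hz
  expect_identical(1024 / 125, 8.192)

  rconst <- sineRecord(1500L)
  rconst@abp <- rep(100, 1500L)
  wc <- segmentRecord(edgeBP:::conditionRecord(rconst))
  expect_true(all(wc@sbp == 100) && all(wc@dbp == 100))

  short <- sineRecord(1000L)
  expect_message(ws <- segmentRecord(edgeBP:::conditionRecord(short)),
                 "shorter")
  expect_identical(nWindows(ws), 0L)

  # per-window labels are the slice extrema
  ridx <- sample(nWindows(w2), 1)
  sl <- (w2@startIndex[ridx] + 1):(w2@startIndex[ridx] + 1024)
  expect_identical(w2@sbp[ridx], max(r2@abp[sl]))
  expect_identical(w2@dbp[ridx], min(r2@abp[sl]))
})

test_that("window counts are conserved across the pipeline", {
  spec <- cohortSpec(nRecords = 4L, durationS = 30, seed = 6L)
  coh <- generateCohort(spec)
  ws <- preprocessCohort(coh, minDurationS = 20)
  expected <- sum(vapply(records(coh), function(r)
    (length(r@ppg) - 1024L) %/% 256L + 1L, integer(1)))
  expect_identical(nWindows(ws), expected)
  expect_true(all(ws@values >= 0 & ws@values <= 1))
  expect_true(all(ws@dbp <= ws@sbp))
})

test_that("zero-noise windows reproduce generator ground truth exactly", {
  spec <- cohortSpec(noiseSD = 0, wanderAmplitude = 0, driftAmplitude = 0)
  r <- withr::with_seed(4, generateRecord(spec, c(141, 68),
                                          durationS = 30))
  ws <- segmentRecord(edgeBP:::conditionRecord(r))
  gt <- r@groundTruth
  for (i in seq_len(nWindows(ws))) {
    lo <- ws@startIndex[i] + 1L
    hi <- ws@startIndex[i] + 1024L
    peaks <- gt$sbp[gt$peakIndex >= lo & gt$peakIndex <= hi]
    troughs <- gt$dbp[gt$troughIndex >= lo & gt$troughIndex <= hi]
    if (length(peaks)) expect_equal(ws@sbp[i], max(peaks),
                                    tolerance = 1e-9)
    if (length(troughs)) expect_equal(ws@dbp[i], min(troughs),
                                      tolerance = 1e-9)
  }
})

test_that("split sizes follow the documented rounding rule", {
  ws <- syntheticWindowSet(10L, seed = 2L)
  sp <- assembleSplits(ws, splitSeed = 1L)
  n <- nWindows(sp)
  expect_identical(unname(n["test"]), 3L)     # round(10 * 0.3)
  expect_identical(unname(n["val"]), 1L)      # round(7 * 0.2) = round(1.4)
  expect_identical(unname(n["train"]), 6L)
  expect_error(assembleSplits(ws, testFraction = 1.2), "fractions")
  expect_error(assembleSplits(syntheticWindowSet(5L)), "at least 10")
})

test_that("cross-split duplicates are removed from the test side", {
  ws <- syntheticWindowSet(40L, seed = 3L)
  # force duplicates: make several windows value-identical
  ws@values[2, ] <- ws@values[1, ]
  ws@values[12, ] <- ws@values[1, ]
  ws@values[22, ] <- ws@values[1, ]
  ws@values[32, ] <- ws@values[1, ]
  sp <- assembleSplits(ws, splitSeed = 7L)
  trainKeys <- edgeBP:::windowKeys(rbind(windowValues(sp@train),
                                         windowValues(sp@val)))
  testKeys <- edgeBP:::windowKeys(windowValues(sp@test))
  expect_false(any(testKeys %in% trainKeys))
  expect_identical(sum(nWindows(sp)) + sp@config$nDeduplicated, 40L)
})

test_that("splitting is deterministic and subject-wise mode is disjoint", {
  ws <- syntheticWindowSet(60L, seed = 5L)
  a <- assembleSplits(ws, splitSeed = 9L)
  b <- assembleSplits(ws, splitSeed = 9L)
  expect_identical(windowValues(a@train), windowValues(b@train))
  expect_identical(windowValues(a@test), windowValues(b@test))
  sw <- assembleSplits(ws, splitSeed = 9L, subjectWise = TRUE)
  expect_length(intersect(unique(sw@test@recordId),
                          unique(c(sw@train@recordId,
                                   sw@val@recordId))), 0L)
})

test_that("window datasets round-trip through the CSV container", {
  ws <- syntheticWindowSet(12L, seed = 8L, len = 1024L)
  f <- tempfile(fileext = ".csv")
  writeWindowsCSV(ws, f)
  ws2 <- readWindowsCSV(f)
  expect_equal(windowValues(ws2), windowValues(ws), tolerance = 1e-12)
  expect_identical(ws2@recordId, ws@recordId)
  expect_identical(ws2@startIndex, ws@startIndex)
  expect_equal(ws2@sbp, ws@sbp)
  unlink(f)
})

test_that("moving-average detrending removes slow baseline wander", {
  t <- 1:5000
  slow <- 2 * sin(2 * pi * t / 4000)           # ~16 s period wander
  fast <- sin(2 * pi * t / 100)                # pulse-rate oscillation
  d <- detrendPPG(slow + fast, method = "moving_average", windowS = 2)
  # the slow component is attenuated, the fast one preserved
  expect_lt(sd(d - fast), 0.2 * sd(slow))
  expect_gt(cor(d, fast), 0.97)
})
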