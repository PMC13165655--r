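# Full-integer INT8 engine: quantization parameters, calibration,
# fixed-point requantization and the integer-only executor.

quantToy <- function(seedW = 1L, inputLength = 32L, seedX = 2L, n = 16L) {
  spec <- fullKindsArch(inputLength)
  m <- randomizeBiases(initializeModel(spec, seed = seedW), seed = seedW)
  set.seed(seedX)
  X <- matrix(runif(n * inputLength), n)
  stats <- calibrate(m, X)
  list(model = m, X = X, stats = stats,
       qmodel = quantizeModel(m, stats))
}

test_that("quantization parameters follow the affine formulas", {
  qp <- computeQParams(0, 2.55)
  expect_equal(qp$scale, 0.01)
  expect_identical(qp$zeroPoint, -128L)

  qs <- computeQParams(-1.27, 1.27, symmetric = TRUE)
  expect_equal(qs$scale, 0.01)
  expect_identical(qs$zeroPoint, 0L)

  # zero-nudge: the dequantized grid contains exactly 0
  qn <- computeQParams(-1, 3)
  grid <- (( -128:127) - qn$zeroPoint) * qn$scale
  expect_true(any(grid == 0))

  # degenerate range falls back to a positive epsilon scale
  qd <- computeQParams(0, 0)
  expect_gt(qd$scale, 0)
  expect_error(computeQParams(1, 0), "maxVal")
})

test_that("tensor quantization rounds, clamps and bounds the error", {
  qp <- list(scale = 0.01, zeroPoint = -128L)
  expect_identical(quantizeTensor(1.0, qp), -28L)
  expect_identical(quantizeTensor(99, qp), 127L)     # saturation
  expect_identical(quantizeTensor(-99, qp), -128L)
  set.seed(4)
  x <- runif(1000, 0, 2.55)
  q <- quantizeTensor(x, qp)
  expect_true(all(abs(dequantizeTensor(q, qp) - x) <= qp$scale / 2 + 1e-12))
  # rounding half away from zero, not banker's
  expect_identical(quantizeTensor(0.005, qp), -127L) # 0.5 -> 1
  expect_error(quantizeTensor(NaN, qp), "non-finite")
})

test_that("per-channel quantization applies one scale per output channel", {
  W <- array(c(rep(0.1, 6), rep(10, 6)), dim = c(3, 2, 2))
  sc <- apply(abs(W), 3, max) / 127
  q <- quantizeTensor(W, list(scale = sc, zeroPoint = 0L))
  expect_identical(max(abs(q[, , 1])), 127L)
  expect_identical(max(abs(q[, , 2])), 127L)
  back <- dequantizeTensor(q, list(scale = sc, zeroPoint = 0L))
  expect_true(all(abs(back - W) <= rep(sc, each = 6) / 2))
})

test_that("calibration tracks exact min/max as a lattice", {
  spec <- toyArch(list(
    mkLayer("g", "gap1d", "input"),
    mkLayer("fc", "dense", "g", filters = 2L)), inputLength = 8L)
  m <- initializeModel(spec, seed = 1)
  s1 <- calibrate(m, matrix(0.3, 1, 8))
  # single constant sample: single-valued edges have min == max == value,
  # the two-output head has the elementwise range of its activations
  r1 <- s1@ranges
  expect_identical(r1$min[r1$edge == "input"], 0.3)
  expect_identical(r1$max[r1$edge == "input"], 0.3)
  expect_identical(r1$min[r1$edge == "g"], r1$max[r1$edge == "g"])
  ref <- refForward(m, rep(0.3, 8))
  expect_equal(c(r1$min[r1$edge == "fc"], r1$max[r1$edge == "fc"]),
               range(ref))
  x2 <- matrix(0.9, 1, 8)
  s2 <- calibrate(m, x2)
  s12 <- calibrate(m, rbind(matrix(0.3, 1, 8), x2))
  merged <- merge(s1@ranges, s2@ranges, by = "edge")
  expect_equal(s12@ranges$min[order(s12@ranges$edge)],
               pmin(merged$min.x, merged$min.y)[order(merged$edge)])
  expect_equal(s12@ranges$max[order(s12@ranges$edge)],
               pmax(merged$max.x, merged$max.y)[order(merged$edge)])
  # bitwise reproducibility
  tq <- quantToy()
  expect_identical(calibrate(tq$model, tq$X)@ranges, tq$stats@ranges)
})

test_that("model quantization is deterministic and structure-preserving", {
  tq <- quantToy()
  qm2 <- quantizeModel(tq$model, tq$stats)
  expect_identical(tq$qmodel@layers, qm2@layers)
  for (nm in names(tq$qmodel@layers)) {
    ql <- tq$qmodel@layers[[nm]]
    if (!is.null(ql$Wq)) {
      expect_true(all(ql$Wq >= -127 & ql$Wq <= 127))  # -128 reserved out
      w <- tq$model@weights[[nm]]
      expect_identical(length(ql$Wq), length(w$W))
      expect_identical(length(ql$bq), length(w$b))
    }
  }
  # all-zero weights quantize to all-zero INT8
  m0 <- tq$model
  for (nm in names(m0@weights)) m0@weights[[nm]]$W[] <- 0
  st0 <- calibrate(m0, tq$X)
  qm0 <- suppressMessages(quantizeModel(m0, st0))
  for (nm in names(qm0@layers))
    if (!is.null(qm0@layers[[nm]]$Wq))
      expect_true(all(qm0@layers[[nm]]$Wq == 0L))
})

test_that("requantization matches hand values and the 1-LSB parity bound", {
  expect_identical(requantize(100L, 0.25), 25L)
  expect_identical(requantize(0L, 0.37, zeroPoint = 5L), 5L)
  expect_identical(requantize(c(100L, -100L), 0.25), c(25L, -25L))
  # fixed-point vs float multiplier on a large randomized sweep
  set.seed(11)
  n <- 1e6
  acc <- as.integer(round(runif(n, -2^22, 2^22)))
  M <- runif(n, 1e-6, 0.9999)
  qf <- requantize(acc, M, mode = "fixed")
  ql <- requantize(acc, M, mode = "float")
  expect_lte(max(abs(qf - ql)), 1L)
})

test_that("identity convolution passes integers through unchanged", {
  # 1-tap conv whose weight dequantizes to exactly 1.0 with matched
  # input/output ranges: the integer stream must be the identity
  spec <- toyArch(list(
    mkLayer("c", "conv1d", "input", kernel = 1L, filters = 1L),
    mkLayer("f", "flatten", "c"),
    mkLayer("fc", "dense", "f", filters = 2L)), inputLength = 16L)
  m <- initializeModel(spec, seed = 1)
  m@weights$c$W[] <- 1.0
  m@weights$c$b[] <- 0
  set.seed(3)
  X <- rbind(seq(0, 1, length.out = 16), matrix(runif(3 * 16), 3))
  stats <- calibrate(m, X)
  qm <- quantizeModel(m, stats)
  xq <- quantizeTensor(X[2, ], qm@inputQP)
  acts <- list(input = matrix(xq, ncol = 1))
  ql <- qm@layers$c
  out <- edgeBP:::.conv1d_int8(acts$input, ql$Wq, ql$bq,
                               qm@edges$input$zeroPoint,
                               ql$mant, ql$shift, ql$M,
                               qm@edges$c$zeroPoint, 1L, 1L, 1L, 0L, 0L,
                               TRUE)
  expect_identical(as.integer(out), as.integer(xq))
})

test_that("feeding the zero point yields the zero points everywhere", {
  tq <- quantToy()
  qm <- tq$qmodel
  for (nm in names(qm@layers)) {
    if (!is.null(qm@layers[[nm]]$bq)) qm@layers[[nm]]$bq[] <- 0L
  }
  zpIn <- qm@inputQP$zeroPoint
  xq <- matrix(rep(zpIn, 32L), 1, 32)
  storage.mode(xq) <- "integer"
  out <- forwardInt8(qm, xq)
  expect_identical(as.integer(out$int8[1, ]),
                   rep(qm@outputQP$zeroPoint, 2L))
})

test_that("dequantized INT8 outputs track the float reference", {
  # shallow randomized nets (conv + relu + GAP head, 8 channels): integer
  # outputs stay within 3 output LSBs of the float executor
  for (seed in 1:8) {
    spec <- toyArch(list(
      mkLayer("c", "conv1d", "input", kernel = 3L, filters = 8L),
      mkLayer("r", "relu", "c"),
      mkLayer("g", "gap1d", "r"),
      mkLayer("fc", "dense", "g", filters = 2L)), inputLength = 32L)
    m <- randomizeBiases(initializeModel(spec, seed = seed), seed = seed)
    # mmHg-scale regression head, like a trained pressure model
    m@weights$fc$W <- m@weights$fc$W * 8
    m@weights$fc$b <- c(100, 60)
    set.seed(seed + 100L)
    X <- matrix(runif(16 * 32), 16) * runif(16, 0.2, 1)
    qm <- quantizeModel(m, calibrate(m, X))
    fp <- forwardFloat(m, X)
    qp <- forwardInt8(qm, X)
    lsb <- qm@outputQP$scale
    expect_lt(max(abs(fp - qp$pred)), 3 * lsb + 1e-12)
  }
})

test_that("fixed-point and float-multiplier paths agree end to end", {
  worst <- 0L
  for (seed in 1:100) {
    tq <- quantToy(seedW = seed, seedX = seed + 500L, n = 4L)
    qf <- forwardInt8(tq$qmodel, tq$X, mode = "fixed")
    ql <- forwardInt8(tq$qmodel, tq$X, mode = "float")
    worst <- max(worst, max(abs(qf$int8 - ql$int8)))
  }
  expect_lte(worst, 1L)
})

test_that("single-conv quantization error respects the propagation bound", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(c(1L, 3L, 5L), 1)
    cin <- sample(1:8, 1); cout <- sample(1:8, 1)
    spec <- toyArch(list(
      mkLayer("c", "conv1d", "input", kernel = k, filters = cout),
      mkLayer("f", "flatten", "c"),
      mkLayer("fc", "dense", "f", filters = 2L)), inputLength = 12L)
    m <- initializeModel(spec, seed = rep)
    m@weights$c$b <- rnorm(cout, 0, 0.2)
    X <- matrix(runif(6 * 12), 6)
    stats <- calibrate(m, X)
    qm <- quantizeModel(m, stats)
    ql <- qm@layers$c
    sIn <- qm@inputQP$scale; sOut <- qm@edges$c$scale
    xq <- quantizeTensor(X[1, ], qm@inputQP)
    convInt <- edgeBP:::.conv1d_int8(matrix(xq, ncol = 1), ql$Wq, ql$bq,
                                     qm@inputQP$zeroPoint, ql$mant,
                                     ql$shift, ql$M,
                                     qm@edges$c$zeroPoint,
                                     k, 1L, 1L, ql$pad[1], ql$pad[2], TRUE)
    deq <- (matrix(convInt, ncol = cout) - qm@edges$c$zeroPoint) * sOut
    ref <- refForward(
      new("FloatModel",
          spec = toyArch(list(mkLayer("c", "conv1d", "input", kernel = k,
                                      filters = cout)), 12L),
          weights = list(c = m@weights$c)), X[1, ])
    # error propagation bound computed alongside, per output channel:
    # requant rounding (sOut/2) + per-tap input rounding (|w| sIn/2),
    # weight rounding (|x| sW/2 with |x| <= 1), their cross term
    # (sIn sW / 4), and bias rounding (sIn sW / 2)
    refM <- matrix(ref, ncol = cout)
    for (o in seq_len(cout)) {
      sW <- ql$wScale[o]
      maxW <- max(abs(m@weights$c$W[, , o]))
      taps <- k * cin
      bound <- 0.5 * sOut +
        taps * (maxW * sIn / 2 + sW / 2 + sIn * sW / 4) +
        sIn * sW / 2
      expect_true(all(abs(deq[, o] - refM[, o]) <= bound + 1e-9))
    }
  }
})

test_that("no float value influences the fixed-point integer path", {
  tq <- quantToy()
  base <- forwardInt8(tq$qmodel, tq$X, mode = "fixed")$int8
  jit <- tq$qmodel
  bump <- function(x) x * (1 + .Machine$double.eps)
  for (nm in names(jit@edges)) jit@edges[[nm]]$scale <-
    bump(jit@edges[[nm]]$scale)
  for (nm in names(jit@layers)) {
    for (fld in c("M", "MA", "MB", "wScale"))
      if (!is.null(jit@layers[[nm]][[fld]]))
        jit@layers[[nm]][[fld]] <- bump(jit@layers[[nm]][[fld]])
  }
  jit@inputQP$scale <- bump(jit@inputQP$scale)
  jittered <- forwardInt8(jit, matrix(quantizeTensor(tq$X, tq$qmodel@inputQP),
                                      nrow(tq$X), ncol(tq$X)),
                          mode = "fixed")$int8
  expect_identical(base, jittered)
})

test_that("quantized payload bytes follow the documented layout", {
  tq <- quantToy()
  det <- weightsBytes(tq$qmodel, detail = TRUE)
  # spec-walk oracle
  kern <- 0L; bias <- 0L; scales <- 0L
  for (nm in names(tq$model@weights)) {
    w <- tq$model@weights[[nm]]
    kern <- kern + length(w$W)
    bias <- bias + 4L * length(w$b)
    scales <- scales + 4L * length(tq$qmodel@layers[[nm]]$wScale)
  }
  expect_identical(det$kernel, kern)
  expect_identical(det$bias, bias)
  expect_identical(det$table, scales + 5L * length(tq$qmodel@edges))
  expect_identical(det$total, weightsBytes(tq$qmodel))
})
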