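# Losses, schedulers, gradients and the training loop.

test_that("Huber loss matches its closed form on both branches", {
  expect_equal(huberLoss(0.5, 1), 0.125)
  expect_equal(huberLoss(1.0, 1), 0.5)     # continuity at the knee
  expect_equal(huberLoss(3, 1), 2.5)
  expect_equal(huberLoss(-3, 1), 2.5)      # symmetry
  expect_equal(huberLoss(c(0.5, 3), 1), (0.125 + 2.5) / 2)  # mean reduction
  expect_error(huberLoss(1, 0), "delta")
  expect_error(huberLoss(NaN, 1), "finite")
})

test_that("MSE loss is the mean of squares", {
  expect_equal(mseLoss(c(0, 0)), 0)
  expect_equal(mseLoss(c(1, -1)), 1)
  expect_equal(mseLoss(3), 9)
  expect_error(mseLoss(numeric(0)), "empty")
})

test_that("Huber collapses to the quadratic branch once delta exceeds max|e|", {
  set.seed(1)
  e <- rnorm(200)
  delta <- max(abs(e)) + 0.1
  expect_equal(huberLoss(e, delta), mseLoss(e) / 2, tolerance = 1e-12)
  # large-error asymptote: delta*(MAE) - delta^2/2 per element
  big <- c(50, -80, 120)
  expect_equal(huberLoss(big, 1), mean(abs(big)) - 0.5)
})

test_that("default configs encode the per-architecture protocol", {
  b <- defaultTrainConfig("baseline_cnn")
  expect_identical(b@loss, "mse")
  expect_identical(b@optimizer, "adam")
  expect_identical(b@maxEpochs, 400L)
  expect_identical(b@learningRate, 1e-3)
  expect_true(is.na(b@earlyStopPatience))

  s <- defaultTrainConfig("residual_cnn_slim")
  expect_identical(s@optimizer, "adamw")
  expect_identical(s@learningRate, 8e-4)
  expect_identical(s@weightDecay, 1e-4)
  expect_identical(s@loss, "huber")
  expect_identical(s@huberDelta, 1.0)
  expect_identical(s@earlyStopPatience, 30L)
  expect_true(s@restoreBest)

  t <- defaultTrainConfig("micro_tcn")
  expect_identical(t@minLR, 1e-6)
  expect_identical(t@plateauFactor, 0.5)
  expect_identical(t@batchSize, 128L)
  expect_identical(t@seed, 42L)
})

test_that("plateau schedule reproduces hand-computed halvings", {
  # improvements at 1-2, plateau afterwards, patience 2:
  # reductions fire after epochs 4 and 6 (wait resets), floored at minLR
  v <- c(1.0, 0.8, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)
  lrs <- plateauSchedule(v, lr0 = 0.1, factor = 0.5, patience = 2L,
                         minLR = 0.02)
  expect_equal(lrs, c(0.1, 0.1, 0.1, 0.1, 0.05, 0.05, 0.025, 0.025))
  lrs2 <- plateauSchedule(rep(1, 12), lr0 = 0.1, factor = 0.1,
                          patience = 1L, minLR = 1e-3)
  expect_equal(min(lrs2), 1e-3)            # floor respected
})

test_that("early stopping is a pure function of the loss sequence", {
  v <- c(5, 4, 3, 3.5, 3.2, 3.1, 3.05)
  es <- earlyStopEpoch(v, patience = 3L)
  expect_identical(es$stop, 6L)            # 3 epochs after best epoch 3
  expect_identical(es$best, 3L)
  es2 <- earlyStopEpoch(v, patience = NA_integer_)
  expect_identical(es2$stop, 7L)
})

test_that("backpropagation matches numerical differentiation", {
  spec <- fullKindsArch(32L)
  m <- randomizeBiases(initializeModel(spec, seed = 3))
  set.seed(9)
  X <- matrix(runif(4 * 32), 4)
  Y <- rbind(rnorm(4, 0, 1), rnorm(4, 0, 1))
  for (loss in c("mse", "huber")) {
    lossOf <- function(model)
      edgeBP:::lossValue(Y - t(forwardFloat(model, X)), loss, 1.0)
    ev <- edgeBP:::evalGraph(m, edgeBP:::asInputCube(X, 32L),
                             keepPool = TRUE)
    e <- Y - get("fc", envir = ev$acts)
    grads <- edgeBP:::backwardGraph(m, ev$acts, ev$pools,
                                    edgeBP:::lossGrad(e, loss, 1.0))
    worst <- 0
    for (nm in names(grads)) for (part in c("W", "b")) {
      w0 <- m@weights[[nm]][[part]]
      ga <- grads[[nm]][[part]]
      idx <- seq_len(min(length(w0), 10L))
      for (i in idx) {
        h <- 1e-6
        mp <- m; mp@weights[[nm]][[part]][i] <- w0[i] + h
        mm <- m; mm@weights[[nm]][[part]][i] <- w0[i] - h
        worst <- max(worst,
                     abs((lossOf(mp) - lossOf(mm)) / (2 * h) - ga[i]))
      }
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("a one-parameter head recovers the label mean", {
  # GAP -> dense on constant labels: convex in the bias
  spec <- toyArch(list(
    mkLayer("g", "gap1d", "input"),
    mkLayer("fc", "dense", "g", filters = 2L)), inputLength = 16L)
  set.seed(2)
  n <- 60L
  # constant-valued windows at varying levels: the GAP feature spans (0, 1)
  # and the quadratic fit in (W, b) is identifiable
  ws <- new("WindowSet", values = matrix(rep(runif(n), 16L), n, 16L),
            sbp = rep(100, n), dbp = rep(60, n),
            recordId = rep("r", n), startIndex = rep(0L, n))
  sp <- assembleSplits(ws, splitSeed = 1L)
  cfg <- defaultTrainConfig("toy")
  cfg@loss <- "mse"
  cfg@maxEpochs <- 400L
  cfg@learningRate <- 0.05
  cfg@plateauPatience <- 20L
  cfg@minLR <- 1e-5
  cfg@earlyStopPatience <- NA_integer_
  res <- trainModel(spec, sp, cfg)
  pred <- forwardFloat(res@model, windowValues(sp@val))
  expect_lt(max(abs(pred[, "sbp"] - 100)), 1e-2)
  expect_lt(max(abs(pred[, "dbp"] - 60)), 1e-2)
})

test_that("training improves validation loss and restores the best epoch", {
  spec <- cohortSpec(nRecords = 12L, durationS = 60, noiseSD = 0,
                     driftAmplitude = 0, seed = 21L)
  ws <- preprocessCohort(generateCohort(spec), minDurationS = 30)
  sp <- assembleSplits(ws, splitSeed = 2L)
  arch <- toyArch(list(
    mkLayer("c1", "conv1d", "input", kernel = 5L, filters = 8L),
    mkLayer("r1", "relu", "c1"),
    mkLayer("p1", "maxpool1d", "r1", kernel = 4L),
    mkLayer("c2", "conv1d", "p1", kernel = 5L, filters = 16L),
    mkLayer("r2", "relu", "c2"),
    mkLayer("p2", "maxpool1d", "r2", kernel = 4L),
    mkLayer("g", "gap1d", "p2"),
    mkLayer("fc", "dense", "g", filters = 2L)), inputLength = 1024L)
  cfg <- defaultTrainConfig("small_cnn", profile = "fast")
  cfg@loss <- "mse"
  cfg@maxEpochs <- 12L
  cfg@learningRate <- 3e-3
  cfg@batchSize <- 32L
  res <- trainModel(arch, sp, cfg)
  expect_identical(res@bestEpoch,
                   which.min(res@history$valLoss))
  expect_lt(min(res@history$valLoss), res@history$valLoss[1])
  # restored weights reproduce the best validation loss
  pred <- forwardFloat(res@model, windowValues(sp@val))
  e <- cbind(sp@val@sbp, sp@val@dbp) - pred
  expect_equal(mseLoss(e),
               res@history$valLoss[res@bestEpoch], tolerance = 1e-9)
})

test_that("training is deterministic under a fixed seed", {
  spec <- toyArch(list(
    mkLayer("c1", "conv1d", "input", kernel = 3L, filters = 4L),
    mkLayer("r1", "relu", "c1"),
    mkLayer("g", "gap1d", "r1"),
    mkLayer("fc", "dense", "g", filters = 2L)), inputLength = 64L)
  set.seed(10)
  n <- 40L
  ws <- new("WindowSet", values = matrix(runif(n * 64), n),
            sbp = rnorm(n, 120, 10), dbp = rnorm(n, 70, 5),
            recordId = rep("r", n), startIndex = rep(0L, n))
  sp <- assembleSplits(ws, splitSeed = 3L)
  cfg <- defaultTrainConfig("toy", profile = "fast")
  cfg@maxEpochs <- 3L
  r1 <- trainModel(spec, sp, cfg)
  r2 <- trainModel(spec, sp, cfg)
  expect_identical(r1@history, r2@history)
  expect_identical(r1@model@weights, r2@model@weights)
})

test_that("training configs load from YAML field-for-field", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("learningRate: 0.002", "batchSize: 64",
               "loss: huber", "huberDelta: 2.0"), f)
  cfg <- trainConfigFromYAML(f, name = "micro_tcn")
  expect_identical(cfg@learningRate, 0.002)
  expect_identical(cfg@batchSize, 64L)
  expect_identical(cfg@huberDelta, 2.0)
  expect_identical(cfg@optimizer, "adamw")   # default preserved
  writeLines("nonsenseField: 3", f)
  expect_error(trainConfigFromYAML(f), "unknown training config field")
  unlink(f)
})
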