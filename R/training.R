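## Training engine: losses, Adam/AdamW, reduce-on-plateau scheduling, early
## stopping with best-weight restoration, and the hand-written backward pass
## through the layer DAG (verified against numerical differentiation in the
## test suite).

#' Huber loss
#'
#' Per element: e^2/2 when |e| <= delta, otherwise delta*|e| - delta^2/2;
#' the reduction is the mean over all elements (both outputs, all samples).
#' Combines the stability of the quadratic loss for small errors with the
#' robustness of the absolute loss for outliers.
#'
#' @param errors numeric vector/matrix of signed errors (mmHg).
#' @param delta transition threshold (> 0); the study default is 1.0.
#' @return scalar mean loss.
#' @examples
#' huberLoss(0.5, 1)  # 0.125
#' huberLoss(3, 1)    # 2.5
#' @export
huberLoss <- function(errors, delta = 1.0) {
  stopifnot2(delta > 0, "delta must be > 0")
  stopifnot2(all(is.finite(errors)), "errors must be finite")
  a <- abs(errors)
  mean(ifelse(a <= delta, 0.5 * errors^2, delta * a - 0.5 * delta^2))
}

#' Mean squared error loss
#' @param errors numeric vector/matrix of signed errors.
#' @return scalar mean of squared errors.
#' @export
mseLoss <- function(errors) {
  stopifnot2(length(errors) > 0L, "empty error vector")
  mean(errors^2)
}

# dLoss/dPrediction for errors e = ref - est (matrix outputs x batch)
lossGrad <- function(e, loss, delta) {
  n <- length(e)
  if (loss == "huber") {
    psi <- ifelse(abs(e) <= delta, e, delta * sign(e))
    -psi / n
  } else {
    -2 * e / n
  }
}

lossValue <- function(e, loss, delta)
  if (loss == "huber") huberLoss(e, delta) else mseLoss(e)

#' Default training configuration per architecture
#'
#' The baseline CNN trains with Adam (lr 1e-3), MSE loss and 400 fixed
#' epochs; every other architecture with AdamW (lr 8e-4, weight decay 1e-4),
#' Huber loss (delta 1.0), early stopping (patience 30, best-weight
#' restoration) and reduce-on-plateau (factor 0.5, patience 10, minimum lr
#' 1e-6). Batch size 128 and seed 42 everywhere. The "fast" profile keeps
#' the same optimizer/loss protocol with reduced epoch budgets
#' (desk-scale runs; the full settings remain the default).
#'
#' @param name architecture name.
#' @param profile "paper" (full protocol) or "fast".
#' @return a \linkS4class{TrainConfig}.
#' @export
defaultTrainConfig <- function(name, profile = c("paper", "fast")) {
  profile <- match.arg(profile)
  baseline <- identical(name, "baseline_cnn")
  cfg <- new("TrainConfig",
    optimizer = if (baseline) "adam" else "adamw",
    learningRate = if (baseline) 1e-3 else 8e-4,
    weightDecay = if (baseline) 0 else 1e-4,
    loss = if (baseline) "mse" else "huber",
    huberDelta = 1.0,
    batchSize = 128L,
    maxEpochs = if (baseline) 400L else 200L,
    earlyStopPatience = if (baseline) NA_integer_ else 30L,
    restoreBest = !baseline,
    plateauFactor = 0.5, plateauPatience = 10L, minLR = 1e-6,
    seed = 42L)
  if (profile == "fast") {
    cfg@maxEpochs <- 12L
    if (!baseline) {
      cfg@earlyStopPatience <- 6L
      cfg@plateauPatience <- 3L
    }
  }
  cfg
}

#' Read a training configuration from YAML
#'
#' The file mirrors \linkS4class{TrainConfig} field for field; absent
#' fields keep the defaults of the named architecture's protocol.
#'
#' @param path YAML file path.
#' @param name architecture name supplying the defaults.
#' @param profile default profile, see \code{\link{defaultTrainConfig}}.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfigFromYAML <- function(path, name = "residual_cnn_slim",
                                profile = "paper") {
  cfg <- defaultTrainConfig(name, profile)
  vals <- yaml::read_yaml(path)
  intSlots <- c("batchSize", "maxEpochs", "earlyStopPatience",
                "plateauPatience", "seed")
  for (nm in names(vals)) {
    stopifnot2(nm %in% slotNames(cfg),
               paste("unknown training config field:", nm))
    slot(cfg, nm) <- if (nm %in% intSlots) as.integer(vals[[nm]])
                     else vals[[nm]]
  }
  validObject(cfg)
  cfg
}

## ---- schedulers as pure functions of the validation-loss sequence ----

newPlateauState <- function(lr0, factor, patience, minLR)
  list(lr = lr0, best = Inf, wait = 0L, factor = factor,
       patience = patience, minLR = minLR)

updatePlateau <- function(st, valLoss) {
  if (valLoss < st$best) {
    st$best <- valLoss
    st$wait <- 0L
  } else {
    st$wait <- st$wait + 1L
    if (st$wait >= st$patience) {
      st$lr <- max(st$lr * st$factor, st$minLR)
      st$wait <- 0L
    }
  }
  st
}

#' Learning-rate trajectory of the reduce-on-plateau rule
#'
#' Pure function of a validation-loss sequence: the rate is multiplied by
#' \code{factor} (floored at \code{minLR}) after \code{patience} consecutive
#' epochs without improvement; the reduced rate applies from the next epoch.
#'
#' @param valLosses numeric per-epoch validation losses.
#' @param lr0 initial learning rate.
#' @param factor multiplicative reduction.
#' @param patience epochs without improvement before reducing.
#' @param minLR floor.
#' @return numeric vector: the learning rate in effect at each epoch.
#' @export
plateauSchedule <- function(valLosses, lr0, factor = 0.5, patience = 10L,
                            minLR = 1e-6) {
  st <- newPlateauState(lr0, factor, patience, minLR)
  lrs <- numeric(length(valLosses))
  for (i in seq_along(valLosses)) {
    lrs[i] <- st$lr
    st <- updatePlateau(st, valLosses[i])
  }
  lrs
}

#' Early-stopping decision as a pure function
#'
#' @param valLosses numeric per-epoch validation losses.
#' @param patience epochs without (strict) improvement tolerated.
#' @return list(stop = epoch training stops after (length(valLosses) if it
#'   never triggers), best = epoch of minimal validation loss).
#' @export
earlyStopEpoch <- function(valLosses, patience) {
  best <- 1L; bestLoss <- valLosses[1]
  for (e in seq_along(valLosses)) {
    if (valLosses[e] < bestLoss) { bestLoss <- valLosses[e]; best <- e }
    if (!is.na(patience) && e - best >= patience)
      return(list(stop = e, best = best))
  }
  list(stop = length(valLosses), best = best)
}

## ---- backward pass ----

# gradients of the loss wrt all weights; dOut is dLoss/dSinkOutput
# (n_out x batch)
backwardGraph <- function(model, acts, pools, dOut) {
  layers <- model@spec@layers
  dActs <- new.env(parent = emptyenv())
  addGrad <- function(nm, g) {
    prev <- if (exists(nm, envir = dActs)) get(nm, envir = dActs) else NULL
    assign(nm, if (is.null(prev)) g else prev + g, envir = dActs)
  }
  assign(layers[[length(layers)]]$name, dOut, envir = dActs)
  grads <- list()
  for (ly in rev(layers)) {
    if (!exists(ly$name, envir = dActs)) next
    dy <- get(ly$name, envir = dActs)
    x <- get(ly$inputs[1], envir = acts)
    w <- model@weights[[ly$name]]
    switch(ly$kind,
      conv1d = , pointwise_conv1d = , dilated_causal_conv1d = {
        pad <- convPadding(ly, dim(x)[1])
        r <- .conv1d_bwd(x, w$W, dy, ly$stride, ly$dilation, pad[1], pad[2])
        grads[[ly$name]] <- list(W = r$dW, b = r$db)
        addGrad(ly$inputs[1], r$dx)
      },
      depthwise_conv1d = {
        pad <- convPadding(ly, dim(x)[1])
        r <- .dwconv1d_bwd(x, w$W, dy, ly$stride, ly$dilation,
                           pad[1], pad[2])
        grads[[ly$name]] <- list(W = r$dW, b = r$db)
        addGrad(ly$inputs[1], r$dx)
      },
      relu = addGrad(ly$inputs[1], dy * (x > 0)),
      maxpool1d = addGrad(ly$inputs[1],
                          .maxpool1d_bwd(dy, get(ly$name, envir = pools),
                                         dim(x)[1])),
      gap1d = {
        d <- dim(x)
        addGrad(ly$inputs[1],
                array(rep(dy / d[1], each = d[1]), dim = d))
      },
      flatten = addGrad(ly$inputs[1], array(dy, dim = dim(x))),
      dense = {
        if (!is.matrix(x)) x <- matrix(x, length(x), 1L)
        grads[[ly$name]] <- list(W = x %*% t(dy), b = rowSums(dy))
        addGrad(ly$inputs[1], w$W %*% dy)
      },
      add = {
        addGrad(ly$inputs[1], dy)
        addGrad(ly$inputs[2], dy)
      })
  }
  grads
}

## ---- optimizer ----

newAdamState <- function(weights)
  list(t = 0L,
       m = lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0)),
       v = lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0)))

adamUpdate <- function(weights, grads, state, lr, weightDecay = 0,
                       decoupled = FALSE, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      state$m[[nm]][[part]] <- beta1 * state$m[[nm]][[part]] + (1 - beta1) * g
      state$v[[nm]][[part]] <- beta2 * state$v[[nm]][[part]] +
        (1 - beta2) * g^2
      step <- lr * (state$m[[nm]][[part]] / c1) /
        (sqrt(state$v[[nm]][[part]] / c2) + eps)
      if (decoupled && weightDecay > 0)
        step <- step + lr * weightDecay * weights[[nm]][[part]]
      weights[[nm]][[part]] <- weights[[nm]][[part]] - step
    }
  }
  list(weights = weights, state = state)
}

## ---- training loop ----

#' Train a float model
#'
#' Minibatch gradient training of an architecture on a
#' \linkS4class{SplitWindows} dataset under a \linkS4class{TrainConfig}:
#' shuffled batches, Adam or AdamW updates, reduce-on-plateau learning-rate
#' schedule, optional early stopping, and restoration of the
#' best-validation-loss weights. The output head bias is initialized at the
#' training-label means. Identical (data, config) runs are deterministic.
#'
#' @param spec an \linkS4class{ArchSpec}.
#' @param data a \linkS4class{SplitWindows}.
#' @param config a \linkS4class{TrainConfig}.
#' @param verbose print per-epoch progress.
#' @return a \linkS4class{TrainResult}.
#' @export
trainModel <- function(spec, data, config = defaultTrainConfig(spec@name),
                       verbose = FALSE) {
  validObject(config)
  stopifnot2(nWindows(data@train) > 0L && nWindows(data@val) > 0L,
             "train and validation sets must be non-empty")
  X <- windowValues(data@train)
  Y <- rbind(data@train@sbp, data@train@dbp)        # 2 x n
  Xval <- windowValues(data@val)
  Yval <- cbind(data@val@sbp, data@val@dbp)         # n x 2

  model <- initializeModel(spec, seed = config@seed,
                           outputBias = rowMeans(Y))
  state <- newAdamState(model@weights)
  plateau <- newPlateauState(config@learningRate, config@plateauFactor,
                             config@plateauPatience, config@minLR)
  n <- ncol(Y)
  sink <- sinkLayerName(spec)
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric(), lr = numeric())
  best <- list(epoch = 0L, loss = Inf, weights = model@weights)

  valLossOf <- function() {
    pred <- forwardFloat(model, Xval)
    lossValue(Yval - pred, config@loss, config@huberDelta)
  }

  withSeed(config@seed + 1L, {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(n)
      batchLosses <- numeric(0)
      for (s in seq.int(1L, n, by = config@batchSize)) {
        idx <- ord[s:min(s + config@batchSize - 1L, n)]
        cube <- asInputCube(X[idx, , drop = FALSE], spec@inputLength)
        ev <- evalGraph(model, cube, keepPool = TRUE)
        pred <- get(sink, envir = ev$acts)            # 2 x b
        e <- Y[, idx, drop = FALSE] - pred
        if (!all(is.finite(e)))
          stop("training diverged: non-finite loss at epoch ", epoch)
        batchLosses <- c(batchLosses,
                         lossValue(e, config@loss, config@huberDelta))
        grads <- backwardGraph(model, ev$acts, ev$pools,
                               lossGrad(e, config@loss, config@huberDelta))
        upd <- adamUpdate(model@weights, grads, state, plateau$lr,
                          weightDecay = config@weightDecay,
                          decoupled = config@optimizer == "adamw")
        model@weights <- upd$weights
        state <- upd$state
      }
      vl <- valLossOf()
      history[epoch, ] <- list(epoch, mean(batchLosses), vl, plateau$lr)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                        epoch, mean(batchLosses), vl, plateau$lr))
      if (vl < best$loss)
        best <- list(epoch = epoch, loss = vl, weights = model@weights)
      plateau <- updatePlateau(plateau, vl)
      if (!is.na(config@earlyStopPatience) &&
          epoch - best$epoch >= config@earlyStopPatience) break
    }
  })
  stopped <- nrow(history)
  if (config@restoreBest) model@weights <- best$weights
  new("TrainResult", model = model, history = history,
      stoppedEpoch = as.integer(stopped),
      bestEpoch = as.integer(if (config@restoreBest) best$epoch
                             else stopped))
}
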