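## Neutral float executor. Activations live either in the "conv domain"
## (array length x channels x batch) or the "flat domain" (matrix units x
## batch, produced by flatten/gap/dense). Flatten order is channel-major
## (time index fastest), matching both the column-major R layout and the
## integer executor.

asInputCube <- function(x, inputLength) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot2(ncol(x) == inputLength,
             sprintf("windows must have %d samples", inputLength))
  array(t(x), dim = c(inputLength, 1L, nrow(x)))
}

# evaluate the DAG; returns environment of activations keyed by layer name
# (plus "input"), and pooling argmax indices when keepPool
evalGraph <- function(model, cube, keepPool = FALSE) {
  acts <- new.env(parent = emptyenv())
  pools <- new.env(parent = emptyenv())
  assign("input", cube, envir = acts)
  for (ly in model@spec@layers) {
    xs <- lapply(ly$inputs, get, envir = acts)
    x <- xs[[1]]
    w <- model@weights[[ly$name]]
    out <- switch(ly$kind,
      conv1d = , pointwise_conv1d = , dilated_causal_conv1d = {
        pad <- convPadding(ly, dim(x)[1])
        .conv1d_fwd(x, w$W, w$b, ly$stride, ly$dilation, pad[1], pad[2])
      },
      depthwise_conv1d = {
        pad <- convPadding(ly, dim(x)[1])
        .dwconv1d_fwd(x, w$W, w$b, ly$stride, ly$dilation, pad[1], pad[2])
      },
      relu = pmax(x, 0),
      maxpool1d = {
        r <- .maxpool1d_fwd(x, ly$kernel)
        if (keepPool) assign(ly$name, r$idx, envir = pools)
        r$y
      },
      gap1d = colMeans(x),                      # (channels x batch)
      flatten = {
        d <- dim(x)
        matrix(x, d[1] * d[2], d[3])
      },
      dense = {
        if (!is.matrix(x)) x <- matrix(x, length(x), 1L)
        crossprod(w$W, x) + w$b                 # (n_out x batch)
      },
      add = xs[[1]] + xs[[2]])
    assign(ly$name, out, envir = acts)
  }
  list(acts = acts, pools = pools)
}

sinkLayerName <- function(spec) spec@layers[[length(spec@layers)]]$name

#' Run float inference
#'
#' Evaluates the layer DAG in topological order on one or more PPG windows
#' and returns SBP/DBP estimates in mmHg. This executor is also the parity
#' oracle for the integer engine.
#'
#' @param model a \linkS4class{FloatModel}.
#' @param x numeric vector of 1024 samples, or a matrix (windows x 1024), or
#'   a \linkS4class{WindowSet}.
#' @param batchSize internal evaluation chunk size.
#' @return matrix (windows x 2) with columns sbp, dbp.
#' @export
forwardFloat <- function(model, x, batchSize = 256L) {
  if (is(x, "WindowSet")) x <- windowValues(x)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n <- nrow(x)
  out <- matrix(NA_real_, n, 2L,
                dimnames = list(NULL, c("sbp", "dbp")))
  sink <- sinkLayerName(model@spec)
  for (s in seq.int(1L, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, n)
    cube <- asInputCube(x[idx, , drop = FALSE], model@spec@inputLength)
    y <- get(sink, envir = evalGraph(model, cube)$acts)
    if (!all(is.finite(y))) stop("non-finite values in forward pass")
    out[idx, ] <- t(y)
  }
  out
}

# forward pass that accumulates per-edge (min, max) over a batch, merged
# into `ranges` (a named list of c(min, max))
forwardRanges <- function(model, x, ranges = list()) {
  cube <- asInputCube(x, model@spec@inputLength)
  acts <- evalGraph(model, cube)$acts
  for (nm in c("input", names(model@spec@layers))) {
    v <- range(get(nm, envir = acts))
    prev <- ranges[[nm]]
    ranges[[nm]] <- if (is.null(prev)) v
                    else c(min(prev[1], v[1]), max(prev[2], v[2]))
  }
  ranges
}

#' Initialize float weights for an architecture
#'
#' He-normal kernels (SD sqrt(2 / fan_in)) for convolutions and hidden dense
#' layers, zero biases. The output head regresses raw mmHg, so its bias can
#' optionally be started at supplied label means (a standard regression-head
#' initialization that removes the large constant offset from the first
#' optimization steps).
#'
#' @param spec an \linkS4class{ArchSpec}.
#' @param seed RNG seed.
#' @param outputBias optional length-2 numeric, initial SBP/DBP head bias.
#' @return a \linkS4class{FloatModel}.
#' @export
initializeModel <- function(spec, seed = 42L, outputBias = NULL) {
  shapes <- inferShapes(spec)
  sink <- sinkLayerName(spec)
  withSeed(seed, {
    weights <- list()
    for (ly in spec@layers) {
      inShape <- shapes[[ly$inputs[1]]]
      w <- switch(ly$kind,
        conv1d = , pointwise_conv1d = , dilated_causal_conv1d = {
          fanIn <- ly$kernel * inShape[2]
          list(W = array(rnorm(ly$kernel * inShape[2] * ly$filters,
                               0, sqrt(2 / fanIn)),
                         dim = c(ly$kernel, inShape[2], ly$filters)),
               b = numeric(ly$filters))
        },
        depthwise_conv1d = {
          list(W = matrix(rnorm(ly$kernel * inShape[2],
                                0, sqrt(2 / ly$kernel)),
                          ly$kernel, inShape[2]),
               b = numeric(inShape[2]))
        },
        dense = {
          nIn <- prod(inShape)
          list(W = matrix(rnorm(nIn * ly$filters, 0, sqrt(2 / nIn)),
                          nIn, ly$filters),
               b = numeric(ly$filters))
        },
        NULL)
      if (!is.null(w)) weights[[ly$name]] <- w
    }
    if (!is.null(outputBias))
      weights[[sink]]$b <- as.numeric(outputBias)
    new("FloatModel", spec = spec, weights = weights)
  })
}
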