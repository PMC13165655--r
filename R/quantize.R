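## Full-integer INT8 post-training quantization.
##
## Scheme (the de-facto full-integer convention): per-channel symmetric INT8
## weights (stored range [-127, 127], -128 unused), per-tensor asymmetric
## INT8 activations calibrated by plain min/max over a representative set,
## INT32 biases at scale s_in * s_w, INT8 input and output tensors, no
## retraining. Every requantization multiplier s_in * s_w / s_out is
## decomposed once into a 31-bit mantissa and right shift at quantization
## time; fixed-point inference then uses only those integers. Rounding is
## half away from zero everywhere.

#' Compute quantization parameters from a dynamic range
#'
#' Asymmetric: the range is first widened to include 0, then
#' scale = (max - min)/255 and zero_point = round(-128 - min/scale) clamped
#' to [-128, 127]; real 0 is exactly representable (zero nudging).
#' Symmetric: scale = max(|min|, |max|)/127 with zero_point 0. A degenerate
#' (zero-width) range falls back to a minimal positive scale of 1e-8.
#'
#' @param minVal,maxVal observed range (minVal <= maxVal).
#' @param symmetric logical.
#' @param bits bit width (8).
#' @return list(scale, zeroPoint, symmetric).
#' @examples
#' computeQParams(0, 2.55)$scale        # 0.01
#' computeQParams(0, 2.55)$zeroPoint    # -128
#' @export
computeQParams <- function(minVal, maxVal, symmetric = FALSE, bits = 8L) {
  stopifnot2(maxVal >= minVal, "maxVal must be >= minVal")
  stopifnot2(bits == 8L, "only 8-bit quantization is supported")
  if (symmetric) {
    a <- max(abs(minVal), abs(maxVal))
    scale <- if (a > 0) a / 127 else 1e-8
    return(list(scale = scale, zeroPoint = 0L, symmetric = TRUE))
  }
  lo <- min(minVal, 0); hi <- max(maxVal, 0)
  if (hi == lo)
    return(list(scale = 1e-8, zeroPoint = 0L, symmetric = FALSE))
  scale <- (hi - lo) / 255
  zp <- as.integer(max(-128, min(127, roundHalfAway(-128 - lo / scale))))
  list(scale = scale, zeroPoint = zp, symmetric = FALSE)
}

#' Quantize / dequantize a tensor
#'
#' \code{quantizeTensor}: q = clamp(round(x/scale) + zero_point, -128, 127),
#' rounding half away from zero. Per-channel parameters (a scale vector)
#' apply along the last dimension (the output-channel axis).
#'
#' @param x numeric vector/matrix/array.
#' @param qp list(scale, zeroPoint) from \code{\link{computeQParams}}; scale
#'   may be a vector for per-channel quantization.
#' @return integer tensor of the same shape (INT8 values).
#' @export
quantizeTensor <- function(x, qp) {
  stopifnot2(all(is.finite(x)), "cannot quantize non-finite values")
  scale <- qp$scale
  if (length(scale) > 1L) {
    d <- dim(x)
    ch <- d[length(d)]
    stopifnot2(length(scale) == ch,
               "per-channel scale length must match the last dimension")
    perCh <- prod(d[-length(d)])
    scale <- rep(scale, each = perCh)
  }
  q <- roundHalfAway(x / scale) + qp$zeroPoint
  out <- as.integer(pmin(127, pmax(-128, q)))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' @rdname quantizeTensor
#' @param q integer tensor of INT8 values.
#' @export
dequantizeTensor <- function(q, qp) {
  scale <- qp$scale
  if (length(scale) > 1L) {
    d <- dim(q)
    scale <- rep(scale, each = prod(d[-length(d)]))
  }
  out <- (as.numeric(q) - qp$zeroPoint) * scale
  if (!is.null(dim(q))) dim(out) <- dim(q)
  out
}

#' Requantize INT32 accumulators to INT8
#'
#' Computes round(M * acc) + zero_point clamped to [-128, 127]. In
#' fixed-point mode M is decomposed as mantissa * 2^-shift (31-bit mantissa)
#' and the product is carried in 64-bit integers; the float-multiplier mode
#' is retained for debugging and agrees within 1 LSB.
#'
#' @param acc integer accumulator vector.
#' @param multiplier positive real rescaling factor (scalar or one per
#'   element).
#' @param zeroPoint output zero point.
#' @param mode "fixed" or "float".
#' @return integer vector of INT8 values.
#' @examples
#' requantize(100L, 0.25)  # 25
#' @export
requantize <- function(acc, multiplier, zeroPoint = 0L,
                       mode = c("fixed", "float")) {
  mode <- match.arg(mode)
  qm <- lapply(multiplier, .quantize_multiplier)
  .requantize_int(as.numeric(acc),
                  vapply(qm, `[[`, integer(1), "mantissa"),
                  vapply(qm, `[[`, integer(1), "shift"),
                  as.numeric(multiplier), as.integer(zeroPoint),
                  mode == "fixed")
}

#' Calibrate activation dynamic ranges
#'
#' Runs the float executor over a representative set of windows (drawn from
#' the training split) and tracks the global (min, max) of every activation
#' edge, including the input. Plain min/max, no percentile clipping;
#' deterministic given the sample set.
#'
#' @param model a \linkS4class{FloatModel}.
#' @param representative a \linkS4class{WindowSet} or matrix of windows
#'   (rows); the study protocol uses 512 randomly selected training windows.
#' @param batchSize evaluation chunk size.
#' @return a \linkS4class{CalibrationStats}.
#' @export
calibrate <- function(model, representative, batchSize = 128L) {
  x <- if (is(representative, "WindowSet")) windowValues(representative)
       else representative
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  ranges <- list()
  for (s in seq.int(1L, nrow(x), by = batchSize))
    ranges <- forwardRanges(model,
                            x[s:min(s + batchSize - 1L, nrow(x)), ,
                              drop = FALSE], ranges)
  new("CalibrationStats",
      ranges = data.frame(edge = names(ranges),
                          min = vapply(ranges, `[`, numeric(1), 1L),
                          max = vapply(ranges, `[`, numeric(1), 2L),
                          row.names = NULL),
      nSamples = nrow(x))
}

# INT32 bias quantization at scale s_in * s_w, saturating at the INT32 range
quantizeBias <- function(b, scale) {
  q <- roundHalfAway(b / scale)
  as.integer(pmin(2147483647, pmax(-2147483647, q)))
}

# consumers of each activation edge
edgeConsumers <- function(spec) {
  cons <- list()
  for (ly in spec@layers)
    for (nm in ly$inputs)
      cons[[nm]] <- c(cons[[nm]], ly$name)
  cons
}

#' Quantize a float model to full-integer INT8
#'
#' Converts weights to per-channel symmetric INT8 and biases to INT32 at
#' scale s_in * s_w; assigns per-tensor asymmetric activation parameters
#' from the calibration statistics (a convolution or dense layer feeding
#' only a ReLU adopts the post-activation range, fusing the ReLU into its
#' output clamp; max pooling and flatten inherit their input edge without
#' requantization); and precomputes all fixed-point requantization
#' multipliers. No weight value is altered beyond rounding — there is no
#' retraining.
#'
#' @param model a trained \linkS4class{FloatModel}.
#' @param stats a \linkS4class{CalibrationStats} covering every edge.
#' @return a \linkS4class{QuantizedModel}.
#' @export
quantizeModel <- function(model, stats) {
  spec <- model@spec
  shapes <- inferShapes(spec)
  ranges <- split(stats@ranges[, c("min", "max")], stats@ranges$edge)
  ranges <- lapply(ranges, unlist)
  for (nm in c("input", names(spec@layers)))
    stopifnot2(nm %in% names(ranges),
               paste("calibration does not cover edge:", nm))
  cons <- edgeConsumers(spec)
  kindOf <- function(nm) if (nm == "input") "input" else spec@layers[[nm]]$kind

  edges <- list(input = computeQParams(ranges$input[1], ranges$input[2]))
  for (ly in spec@layers) {
    edges[[ly$name]] <- switch(ly$kind,
      relu = , maxpool1d = , flatten = edges[[ly$inputs[1]]],
      {
        r <- ranges[[ly$name]]
        co <- cons[[ly$name]]
        if (length(co) == 1L && kindOf(co) == "relu")
          r <- ranges[[co]]                    # fuse the ReLU range
        if (r[2] - max(r[1], 0) <= 0 && r[1] >= 0 && r[2] <= 0)
          message("degenerate activation range on edge ", ly$name,
                  "; using epsilon scale")
        computeQParams(r[1], r[2])
      })
  }

  qlayers <- list()
  for (ly in spec@layers) {
    inEdge <- edges[[ly$inputs[1]]]
    outEdge <- edges[[ly$name]]
    w <- model@weights[[ly$name]]
    ql <- list(kind = ly$kind)
    if (ly$kind %in% CONV_KINDS) {
      d <- dim(w$W)                            # k x Cin x Cout
      wScale <- apply(abs(w$W), 3, max) / 127
      wScale[wScale == 0] <- 1e-8
      Wq <- quantizeTensor(w$W, list(scale = wScale, zeroPoint = 0L))
      # row order tap-major then channel, matching the executors' im2col
      Wm <- matrix(0L, d[1] * d[2], d[3])
      for (o in seq_len(d[3]))
        Wm[, o] <- as.integer(aperm(Wq[, , o, drop = FALSE], c(2, 1, 3)))
      M <- inEdge$scale * wScale / outEdge$scale
      qm <- lapply(M, .quantize_multiplier)
      ql <- c(ql, list(
        Wq = Wm,
        bq = quantizeBias(w$b, inEdge$scale * wScale),
        wScale = wScale, M = M,
        mant = vapply(qm, `[[`, integer(1), "mantissa"),
        shift = vapply(qm, `[[`, integer(1), "shift"),
        kernel = ly$kernel, stride = ly$stride, dilation = ly$dilation,
        pad = convPadding(ly, shapes[[ly$inputs[1]]][1])))
    } else if (ly$kind == "depthwise_conv1d") {
      wScale <- apply(abs(w$W), 2, max) / 127
      wScale[wScale == 0] <- 1e-8
      Wq <- quantizeTensor(w$W, list(scale = wScale, zeroPoint = 0L))
      M <- inEdge$scale * wScale / outEdge$scale
      qm <- lapply(M, .quantize_multiplier)
      ql <- c(ql, list(
        Wq = Wq,
        bq = quantizeBias(w$b, inEdge$scale * wScale),
        wScale = wScale, M = M,
        mant = vapply(qm, `[[`, integer(1), "mantissa"),
        shift = vapply(qm, `[[`, integer(1), "shift"),
        stride = ly$stride, dilation = ly$dilation,
        pad = convPadding(ly, shapes[[ly$inputs[1]]][1])))
    } else if (ly$kind == "dense") {
      wScale <- apply(abs(w$W), 2, max) / 127
      wScale[wScale == 0] <- 1e-8
      Wq <- quantizeTensor(w$W, list(scale = wScale, zeroPoint = 0L))
      M <- inEdge$scale * wScale / outEdge$scale
      qm <- lapply(M, .quantize_multiplier)
      ql <- c(ql, list(
        Wq = Wq,
        bq = quantizeBias(w$b, inEdge$scale * wScale),
        wScale = wScale, M = M,
        mant = vapply(qm, `[[`, integer(1), "mantissa"),
        shift = vapply(qm, `[[`, integer(1), "shift")))
    } else if (ly$kind == "gap1d") {
      L <- shapes[[ly$inputs[1]]][1]
      M <- inEdge$scale / (L * outEdge$scale)
      qm <- .quantize_multiplier(M)
      ql <- c(ql, list(M = M, mant = qm$mantissa, shift = qm$shift))
    } else if (ly$kind == "add") {
      eA <- edges[[ly$inputs[1]]]; eB <- edges[[ly$inputs[2]]]
      MA <- eA$scale / outEdge$scale
      MB <- eB$scale / outEdge$scale
      qA <- .quantize_multiplier(MA); qB <- .quantize_multiplier(MB)
      ql <- c(ql, list(MA = MA, MB = MB,
                       mantA = qA$mantissa, shiftA = qA$shift,
                       mantB = qB$mantissa, shiftB = qB$shift))
    }
    qlayers[[ly$name]] <- ql
  }
  new("QuantizedModel", spec = spec, layers = qlayers, edges = edges,
      inputQP = edges$input, outputQP = edges[[sinkLayerName(spec)]])
}

# integer max pooling (no requantization)
maxpoolInt <- function(x, pool) {
  L <- nrow(x)
  Lout <- L %/% pool
  y <- x[seq.int(1L, Lout * pool, by = pool), , drop = FALSE]
  for (j in seq_len(pool - 1L))
    y <- pmax(y, x[seq.int(1L + j, Lout * pool, by = pool), , drop = FALSE])
  y
}

#' Run integer-only inference
#'
#' Executes the quantized DAG with INT8 tensors: convolutions and dense
#' layers accumulate in 32-bit integers and requantize; ReLU is an integer
#' clamp at the edge zero point; max pooling stays in the integer domain;
#' global average pooling is an integer sum with the 1/L folded into its
#' requantization multiplier; residual adds rescale both addends to the
#' output edge and saturate. In "fixed" mode no floating-point value
#' influences any integer tensor. The final INT8 outputs are dequantized to
#' mmHg.
#'
#' @param qmodel a \linkS4class{QuantizedModel}.
#' @param x numeric vector/matrix of PPG windows (quantized internally with
#'   the model's input parameters), or an integer matrix of pre-quantized
#'   INT8 windows, or a \linkS4class{WindowSet}.
#' @param mode "fixed" (fixed-point multipliers) or "float" (float
#'   multiplier debug path).
#' @return list(pred = matrix (windows x 2) in mmHg,
#'   int8 = matrix (windows x 2) of raw INT8 outputs).
#' @export
forwardInt8 <- function(qmodel, x, mode = c("fixed", "float")) {
  mode <- match.arg(mode)
  fixed <- mode == "fixed"
  if (is(x, "WindowSet")) x <- windowValues(x)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!is.integer(x))
    x <- matrix(quantizeTensor(x, qmodel@inputQP), nrow(x), ncol(x))
  spec <- qmodel@spec
  n <- nrow(x)
  pred <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("sbp", "dbp")))
  rawOut <- matrix(NA_integer_, n, 2L,
                   dimnames = list(NULL, c("sbp", "dbp")))
  outQP <- qmodel@outputQP
  for (i in seq_len(n)) {
    acts <- list(input = matrix(x[i, ], ncol = 1L))
    for (ly in spec@layers) {
      a <- acts[[ly$inputs[1]]]
      ql <- qmodel@layers[[ly$name]]
      zpIn <- qmodel@edges[[ly$inputs[1]]]$zeroPoint
      zpOut <- qmodel@edges[[ly$name]]$zeroPoint
      out <- switch(ly$kind,
        conv1d = , pointwise_conv1d = , dilated_causal_conv1d =
          .conv1d_int8(a, ql$Wq, ql$bq, zpIn, ql$mant, ql$shift, ql$M,
                       zpOut, ql$kernel, ql$stride, ql$dilation,
                       ql$pad[1], ql$pad[2], fixed),
        depthwise_conv1d =
          .dwconv1d_int8(a, ql$Wq, ql$bq, zpIn, ql$mant, ql$shift, ql$M,
                         zpOut, ql$stride, ql$dilation,
                         ql$pad[1], ql$pad[2], fixed),
        dense = .dense_int8(as.integer(a), ql$Wq, ql$bq, zpIn,
                            ql$mant, ql$shift, ql$M, zpOut, fixed),
        relu = pmax(a, zpOut),
        maxpool1d = maxpoolInt(a, ly$kernel),
        gap1d = .gap_int8(a, zpIn, ql$mant, ql$shift, ql$M, zpOut, fixed),
        flatten = matrix(as.integer(a), ncol = 1L),
        add = {
          b <- acts[[ly$inputs[2]]]
          .add_int8(a, b,
                    qmodel@edges[[ly$inputs[1]]]$zeroPoint,
                    qmodel@edges[[ly$inputs[2]]]$zeroPoint,
                    ql$mantA, ql$shiftA, ql$MA,
                    ql$mantB, ql$shiftB, ql$MB, zpOut, fixed)
        })
      if (ly$kind %in% c("conv1d", "pointwise_conv1d",
                         "dilated_causal_conv1d", "depthwise_conv1d") &&
          !is.matrix(out)) out <- matrix(out, ncol = length(ql$M))
      acts[[ly$name]] <- out
    }
    q <- as.integer(acts[[sinkLayerName(spec)]])
    rawOut[i, ] <- q
    pred[i, ] <- (q - outQP$zeroPoint) * outQP$scale
  }
  list(pred = pred, int8 = rawOut)
}
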