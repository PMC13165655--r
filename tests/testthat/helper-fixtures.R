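# Shared fixtures: toy architectures, a nested-loop reference evaluator
# (independent of the package's im2col/GEMM path), and small data builders.

mkLayer <- edgeBP:::makeLayer

toyArch <- function(layers, inputLength = 32L, name = "toy") {
  names(layers) <- vapply(layers, `[[`, "", "name")
  new("ArchSpec", name = name, layers = layers,
      declaredParams = NA_integer_, inputLength = as.integer(inputLength))
}

# random biases keep activations off the exact ReLU kink that zero biases +
# zero padding would create
randomizeBiases <- function(model, seed = 7L) {
  set.seed(seed)
  for (nm in names(model@weights))
    model@weights[[nm]]$b <- rnorm(length(model@weights[[nm]]$b), 0, 0.3)
  model
}

# a toy net touching every layer kind
fullKindsArch <- function(inputLength = 32L) {
  toyArch(list(
    mkLayer("c1", "conv1d", "input", kernel = 3L, filters = 4L,
            stride = 2L),
    mkLayer("r1", "relu", "c1"),
    mkLayer("d1", "dilated_causal_conv1d", "r1", kernel = 3L, filters = 4L,
            dilation = 2L, padding = "causal"),
    mkLayer("a1", "add", c("d1", "r1")),
    mkLayer("r2", "relu", "a1"),
    mkLayer("dw", "depthwise_conv1d", "r2", kernel = 3L, stride = 2L),
    mkLayer("dr", "relu", "dw"),
    mkLayer("pw", "pointwise_conv1d", "dr", kernel = 1L, filters = 6L),
    mkLayer("p1", "maxpool1d", "pw", kernel = 2L),
    mkLayer("g", "gap1d", "p1"),
    mkLayer("fc", "dense", "g", filters = 2L)), inputLength)
}

# ---- nested-loop reference evaluator (brute force, no im2col/GEMM) ----

refForward <- function(model, window) {
  spec <- model@spec
  acts <- list(input = matrix(window, ncol = 1L))
  for (ly in spec@layers) {
    x <- acts[[ly$inputs[1]]]
    w <- model@weights[[ly$name]]
    L <- nrow(x); Cin <- ncol(x)
    out <- switch(ly$kind,
      conv1d = , pointwise_conv1d = , dilated_causal_conv1d = {
        pad <- edgeBP:::convPadding(ly, L)
        k <- ly$kernel; Cout <- ly$filters
        effk <- (k - 1) * ly$dilation + 1
        Lout <- (L + pad[1] + pad[2] - effk) %/% ly$stride + 1
        y <- matrix(0, Lout, Cout)
        for (t in seq_len(Lout)) for (o in seq_len(Cout)) {
          acc <- w$b[o]
          for (tap in seq_len(k)) for (c in seq_len(Cin)) {
            p <- (t - 1) * ly$stride - pad[1] + (tap - 1) * ly$dilation + 1
            if (p >= 1 && p <= L) acc <- acc + x[p, c] * w$W[tap, c, o]
          }
          y[t, o] <- acc
        }
        y
      },
      depthwise_conv1d = {
        pad <- edgeBP:::convPadding(ly, L)
        k <- ly$kernel
        effk <- (k - 1) * ly$dilation + 1
        Lout <- (L + pad[1] + pad[2] - effk) %/% ly$stride + 1
        y <- matrix(0, Lout, Cin)
        for (t in seq_len(Lout)) for (c in seq_len(Cin)) {
          acc <- w$b[c]
          for (tap in seq_len(k)) {
            p <- (t - 1) * ly$stride - pad[1] + (tap - 1) * ly$dilation + 1
            if (p >= 1 && p <= L) acc <- acc + x[p, c] * w$W[tap, c]
          }
          y[t, c] <- acc
        }
        y
      },
      relu = pmax(x, 0),
      maxpool1d = {
        p <- ly$kernel; Lout <- L %/% p
        y <- matrix(0, Lout, Cin)
        for (t in seq_len(Lout)) for (c in seq_len(Cin))
          y[t, c] <- max(x[((t - 1) * p + 1):(t * p), c])
        y
      },
      gap1d = matrix(colMeans(x), ncol = 1L),
      flatten = matrix(as.vector(x), ncol = 1L),
      dense = matrix(as.vector(t(w$W) %*% as.vector(x) + w$b), ncol = 1L),
      add = x + acts[[ly$inputs[2]]])
    acts[[ly$name]] <- out
  }
  as.vector(acts[[edgeBP:::sinkLayerName(spec)]])
}

# a tiny labeled WindowSet with controllable structure
syntheticWindowSet <- function(n, seed = 1L, len = 1024L) {
  set.seed(seed)
  vals <- matrix(runif(n * len), n, len)
  vals <- (vals - min(vals)) / (max(vals) - min(vals))
  new("WindowSet", values = vals,
      sbp = sbp <- rnorm(n, 139, 20), dbp = sbp - abs(rnorm(n, 70, 10)),
      recordId = rep(sprintf("r%02d", seq_len(max(1, n %/% 10))),
                     length.out = n),
      startIndex = as.integer((seq_len(n) - 1) * 256L))
}

# constructed record with sinusoidal channels of a given length
sineRecord <- function(n, id = "sine", abpMax = 120, abpMin = 80) {
  t <- seq_len(n)
  mid <- (abpMax + abpMin) / 2
  amp <- (abpMax - abpMin) / 2
  new("BPRecord", recordId = id, fs = 125L,
      ppg = sin(2 * pi * t / 100) + 0.001 * t / n,
      abp = mid + amp * sin(2 * pi * t / 100),
      groundTruth = data.frame())
}
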