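## Small shared numerics.

# Rounding half away from zero; the convention pinned throughout the
# quantization engine (base::round is round-half-even).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Sample skewness (g1, population-moment form). Used for the right-skew check
# on diastolic targets; the test oracle recomputes it independently.
sampleSkewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

# Nearest-integer with ties rounded up: the documented rounding rule for
# split sizes (e.g. 20% of 7 -> 1.4 -> 1; 2.5 -> 3).
roundHalfUp <- function(x) floor(x + 0.5)

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
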