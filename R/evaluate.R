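## Error metrics, AAMI-style reference checks, FP32/INT8 consistency and
## quantization-drift reporting.

#' Signed estimation errors
#'
#' e_i = reference_i - estimate_i (reference minus estimate).
#'
#' @param ref,est equal-length numeric vectors, mmHg.
#' @return numeric vector of signed errors.
#' @export
signedErrors <- function(ref, est) {
  stopifnot2(length(ref) == length(est) && length(ref) >= 1L,
             "ref and est must have equal positive length")
  ref - est
}

#' Error statistics: ME, SD, MAE
#'
#' Mean error (bias), sample standard deviation of the signed errors (n-1
#' denominator), and mean absolute error, all in mmHg.
#'
#' @param e numeric vector of signed errors (length >= 2).
#' @param target label for the statistic ("SBP" or "DBP").
#' @return one-row data.frame: target, n, me, sd, mae.
#' @examples
#' errorStats(c(2, -2))  # me 0, sd 2.828..., mae 2
#' @export
errorStats <- function(e, target = NA_character_) {
  stopifnot2(length(e) >= 2L, "need at least 2 errors for the SD")
  stopifnot2(all(is.finite(e)), "errors must be finite")
  me <- mean(e)
  out <- data.frame(target = target, n = length(e), me = me,
                    sd = sqrt(sum((e - me)^2) / (length(e) - 1)),
                    mae = mean(abs(e)), stringsAsFactors = FALSE)
  stopifnot2(out$mae >= abs(out$me) - 1e-12,
             "internal error: MAE below |ME|")
  out
}

#' Pearson correlation coefficient
#'
#' Direct implementation of the product-moment form
#' sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) * sum((y - ybar)^2)),
#' used to quantify FP32 vs INT8 prediction consistency.
#'
#' @param x,y equal-length numeric vectors, both non-constant.
#' @return correlation in [-1, 1].
#' @export
pearsonCorr <- function(x, y) {
  stopifnot2(length(x) == length(y) && length(x) >= 2L,
             "x and y must have equal length >= 2")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  stopifnot2(sxx > 0 && syy > 0,
             "Pearson correlation undefined for constant input")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' AAMI-style reference thresholds
#'
#' Flags |ME| <= 5 mmHg and SD < 8 mmHg (strict), the commonly adopted
#' retrospective reference benchmarks. These are advisory comparison labels
#' only: the full AAMI/ESH/ISO standard prescribes prospective subject-level
#' validation and is NOT assessed by a window-level retrospective
#' evaluation.
#'
#' @param stats one-row data.frame from \code{\link{errorStats}}.
#' @return list(mePass, sdPass, note).
#' @examples
#' aamiReferenceCheck(data.frame(me = 5.0, sd = 7.99))   # both TRUE
#' aamiReferenceCheck(data.frame(me = 0, sd = 8.0))      # sdPass FALSE
#' @export
aamiReferenceCheck <- function(stats) {
  list(mePass = abs(stats$me) <= 5,
       sdPass = stats$sd < 8,
       note = paste("reference benchmarks for retrospective comparison,",
                    "not clinical validation"))
}

#' Count physiological-constraint violations
#'
#' Counts prediction pairs with estimated DBP strictly above estimated SBP
#' (DBP <= SBP must hold; equality is not a violation).
#'
#' @param predictions matrix/data.frame with columns sbp, dbp.
#' @return integer count.
#' @export
physiologicalCheck <- function(predictions) {
  p <- as.data.frame(predictions)
  sum(p$dbp > p$sbp)
}

# ME/SD/MAE for both targets from prediction and label matrices
predictionStats <- function(pred, sbpRef, dbpRef) {
  rbind(errorStats(signedErrors(sbpRef, pred[, "sbp"]), "SBP"),
        errorStats(signedErrors(dbpRef, pred[, "dbp"]), "DBP"))
}

#' Quantization-drift report
#'
#' Quantifies the accuracy degradation induced by INT8 conversion: per-target
#' deltas (INT8 minus float) of ME/SD/MAE, AAMI-style flags for both
#' precisions, and an FP32/INT8 consistency block (Pearson correlation per
#' output plus the maximum absolute prediction delta in mmHg).
#'
#' @param floatStats,int8Stats data.frames from \code{predictionStats}-style
#'   evaluation (rows SBP, DBP; columns me, sd, mae) computed on the same
#'   evaluation windows.
#' @param floatPred,int8Pred prediction matrices (windows x 2, columns sbp,
#'   dbp) for the two representations.
#' @return list(drift = data.frame of deltas and flags,
#'   consistency = data.frame with pearson and max |delta|).
#' @export
driftReport <- function(floatStats, int8Stats, floatPred, int8Pred) {
  stopifnot2(nrow(floatPred) == nrow(int8Pred),
             "float and INT8 predictions must cover the same windows")
  stopifnot2(identical(floatStats$target, int8Stats$target),
             "statistic tables must be aligned")
  drift <- data.frame(
    target = floatStats$target,
    dMe = int8Stats$me - floatStats$me,
    dSd = int8Stats$sd - floatStats$sd,
    dMae = int8Stats$mae - floatStats$mae)
  for (i in seq_len(nrow(drift))) {
    fl <- aamiReferenceCheck(floatStats[i, ])
    qt <- aamiReferenceCheck(int8Stats[i, ])
    drift$floatMePass[i] <- fl$mePass; drift$floatSdPass[i] <- fl$sdPass
    drift$int8MePass[i] <- qt$mePass; drift$int8SdPass[i] <- qt$sdPass
  }
  consistency <- data.frame(
    target = c("SBP", "DBP"),
    pearson = c(pearsonCorr(floatPred[, "sbp"], int8Pred[, "sbp"]),
                pearsonCorr(floatPred[, "dbp"], int8Pred[, "dbp"])),
    maxAbsDelta = c(max(abs(floatPred[, "sbp"] - int8Pred[, "sbp"])),
                    max(abs(floatPred[, "dbp"] - int8Pred[, "dbp"]))))
  list(drift = drift, consistency = consistency)
}

#' Binned histogram table
#'
#' Exports the underlying data of distribution figures (true vs predicted
#' values, error distributions) as a plain binned table instead of a
#' rendered plot.
#'
#' @param x numeric vector.
#' @param breaks number of bins or break vector.
#' @return data.frame with bin mid, count, density.
#' @export
histogramTable <- function(x, breaks = 30) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts, density = h$density)
}
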