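## On-disk containers for window datasets and models.
##
## Window sets: a CSV dialect with provenance/label columns first
## (recordId, startIndex, sbp, dbp) followed by the 1024 sample columns
## (v1..v1024), full-precision. Models: an RDS container holding the layer
## graph next to the per-layer named tensors; loaders re-validate the graph
## and every tensor shape before constructing the object.

#' Write / read a window dataset as CSV
#'
#' @param windows a \linkS4class{WindowSet}.
#' @param path file path.
#' @return \code{readWindowsCSV} returns a \linkS4class{WindowSet};
#'   \code{writeWindowsCSV} returns \code{path} invisibly.
#' @export
writeWindowsCSV <- function(windows, path) {
  lab <- windowLabels(windows)
  vals <- windowValues(windows)
  colnames(vals) <- paste0("v", seq_len(ncol(vals)))
  write.csv(cbind(lab[, c("recordId", "startIndex", "sbp", "dbp")],
                  as.data.frame(vals)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowsCSV
#' @export
readWindowsCSV <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  valCols <- grep("^v[0-9]+$", colnames(tab))
  new("WindowSet",
      values = unname(as.matrix(tab[, valCols])),
      sbp = tab$sbp, dbp = tab$dbp,
      recordId = as.character(tab$recordId),
      startIndex = as.integer(tab$startIndex))
}

#' Save / load a float model
#'
#' The container stores the declarative layer graph together with the
#' per-layer named weight tensors; loading re-validates the graph
#' (parameter count against the declared total) and checks every tensor
#' shape against the architecture before returning the model.
#'
#' @param model a \linkS4class{FloatModel}.
#' @param path file path.
#' @return \code{loadFloatModel} returns a \linkS4class{FloatModel};
#'   \code{saveFloatModel} returns \code{path} invisibly.
#' @export
saveFloatModel <- function(model, path) {
  saveRDS(list(format = "edgeBP-float-1",
               name = model@spec@name,
               inputLength = model@spec@inputLength,
               declaredParams = model@spec@declaredParams,
               layers = model@spec@layers,
               weights = model@weights), path)
  invisible(path)
}

#' @rdname saveFloatModel
#' @export
loadFloatModel <- function(path) {
  obj <- readRDS(path)
  stopifnot2(identical(obj$format, "edgeBP-float-1"),
             "not an edgeBP float-model container")
  spec <- new("ArchSpec", name = obj$name, layers = obj$layers,
              declaredParams = obj$declaredParams,
              inputLength = obj$inputLength)
  ref <- initializeModel(spec, seed = 1L)      # shape template
  for (nm in names(ref@weights)) {
    stopifnot2(!is.null(obj$weights[[nm]]),
               paste("missing weights for layer", nm))
    for (part in c("W", "b"))
      stopifnot2(identical(dim(ref@weights[[nm]][[part]]),
                           dim(obj$weights[[nm]][[part]])) &&
                 length(ref@weights[[nm]][[part]]) ==
                   length(obj$weights[[nm]][[part]]),
                 paste("tensor shape mismatch in layer", nm))
  }
  new("FloatModel", spec = spec, weights = obj$weights)
}

#' Save / load a quantized model
#'
#' Stores the INT8 weight tensors, INT32 biases and the per-edge
#' quantization-parameter table next to the layer graph.
#'
#' @param qmodel a \linkS4class{QuantizedModel}.
#' @param path file path.
#' @return \code{loadQuantizedModel} returns a
#'   \linkS4class{QuantizedModel}; \code{saveQuantizedModel} returns
#'   \code{path} invisibly.
#' @export
saveQuantizedModel <- function(qmodel, path) {
  saveRDS(list(format = "edgeBP-int8-1",
               name = qmodel@spec@name,
               inputLength = qmodel@spec@inputLength,
               declaredParams = qmodel@spec@declaredParams,
               specLayers = qmodel@spec@layers,
               layers = qmodel@layers,
               edges = qmodel@edges,
               inputQP = qmodel@inputQP,
               outputQP = qmodel@outputQP), path)
  invisible(path)
}

#' @rdname saveQuantizedModel
#' @export
loadQuantizedModel <- function(path) {
  obj <- readRDS(path)
  stopifnot2(identical(obj$format, "edgeBP-int8-1"),
             "not an edgeBP quantized-model container")
  spec <- new("ArchSpec", name = obj$name, layers = obj$specLayers,
              declaredParams = obj$declaredParams,
              inputLength = obj$inputLength)
  for (nm in c("input", names(spec@layers)))
    stopifnot2(!is.null(obj$edges[[nm]]),
               paste("missing quantization parameters for edge", nm))
  new("QuantizedModel", spec = spec, layers = obj$layers,
      edges = obj$edges, inputQP = obj$inputQP, outputQP = obj$outputQP)
}
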