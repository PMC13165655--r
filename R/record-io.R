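## Per-record on-disk containers.
##
## Two dialects with the identical schema (metadata header + two aligned
## columns):
##  * CSV: comment header lines "#record_id=<id>" and "#fs=<Hz>", then a
##    ppg,abp table (full-precision %.17g).
##  * binary: gzip-compressed stream: magic "EBPR", format version (int32),
##    id length (int32), id bytes (UTF-8), fs (int32), n (int32), n doubles
##    of PPG, n doubles of ABP; little-endian.
## Per-beat ground truth is regenerable from the spec and is not part of the
## container.

#' Write / read a record as CSV
#'
#' @param record a \linkS4class{BPRecord}.
#' @param path file path.
#' @return \code{readRecordCSV} returns a \linkS4class{BPRecord} (with empty
#'   ground truth); \code{writeRecordCSV} returns \code{path} invisibly.
#' @examples
#' r <- generateRecord(cohortSpec(), c(120, 80), durationS = 10)
#' f <- tempfile(fileext = ".csv")
#' writeRecordCSV(r, f)
#' r2 <- readRecordCSV(f)
#' all.equal(r2@abp, r@abp)
#' @export
writeRecordCSV <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#record_id=%s", record@recordId),
               sprintf("#fs=%d", record@fs),
               "ppg,abp"), con)
  writeLines(sprintf("%.17g,%.17g", record@ppg, record@abp), con)
  invisible(path)
}

#' @rdname writeRecordCSV
#' @export
readRecordCSV <- function(path) {
  hdr <- readLines(path, n = 2L)
  id <- sub("^#record_id=", "", hdr[1])
  fs <- as.integer(sub("^#fs=", "", hdr[2]))
  tab <- read.csv(path, comment.char = "#")
  new("BPRecord", recordId = id, fs = fs,
      ppg = as.numeric(tab$ppg), abp = as.numeric(tab$abp),
      groundTruth = data.frame())
}

#' Write / read a record in the compressed binary container
#'
#' @param record a \linkS4class{BPRecord}.
#' @param path file path.
#' @return \code{readRecordBin} returns a \linkS4class{BPRecord};
#'   \code{writeRecordBin} returns \code{path} invisibly.
#' @export
writeRecordBin <- function(record, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("EBPR"), con)
  idRaw <- charToRaw(enc2utf8(record@recordId))
  writeBin(c(1L, length(idRaw)), con, size = 4L, endian = "little")
  writeBin(idRaw, con)
  writeBin(c(record@fs, length(record@ppg)), con, size = 4L,
           endian = "little")
  writeBin(record@ppg, con, size = 8L, endian = "little")
  writeBin(record@abp, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeRecordBin
#' @export
readRecordBin <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  stopifnot2(magic == "EBPR", "not an edgeBP binary record container")
  meta <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  stopifnot2(meta[1] == 1L, "unsupported container version")
  id <- rawToChar(readBin(con, "raw", meta[2]))
  meta2 <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  ppg <- readBin(con, "double", meta2[2], size = 8L, endian = "little")
  abp <- readBin(con, "double", meta2[2], size = 8L, endian = "little")
  new("BPRecord", recordId = id, fs = meta2[1], ppg = ppg, abp = abp,
      groundTruth = data.frame())
}
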