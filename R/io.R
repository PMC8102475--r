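# file formats: TIFF stacks with JSON sidecars, records CSV, map TIFF

#' Write a fluorescence sequence as multi-page TIFF plus JSON sidecar
#'
#' Frames are written as one grayscale TIFF page per frame in integer
#' detector units (8-bit when `detectorMax <= 255`, 16-bit otherwise); the
#' sidecar JSON records `timestamps`, `frame_rate`, `injection_index`,
#' `detector_max` and `bits`. Integer stacks round-trip bit-identically
#' through [readSequence()]. Non-integer frames are an error: quantize at
#' simulation time (`quantize = TRUE`, the default) or keep such stacks in
#' memory.
#'
#' @param seq a [FluorescenceSequence-class] with integer-valued frames.
#' @param path output TIFF file.
#' @param sidecarPath output JSON sidecar (default `<path>.json`).
#' @return `path`, invisibly.
#' @seealso [readSequence()]
#' @export
writeSequence <- function(seq, path, sidecarPath = paste0(path, ".json")) {
  stopifnot(is(seq, "FluorescenceSequence"))
  fr <- frames(seq)
  if (max(abs(fr - round(fr))) > 0)
    stop("frames must be in integer detector units to be written; ",
         "simulate with quantize = TRUE", call. = FALSE)
  dmax <- detectorMax(seq)
  bits <- if (dmax <= 255) 8L else 16L
  scale <- 2^bits - 1
  if (dmax > scale)
    stop("detectorMax exceeds the 16-bit container range", call. = FALSE)
  Tn <- dim(fr)[3L]
  pages <- lapply(seq_len(Tn), function(k) fr[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  meta <- list(timestamps = timestamps(seq), frame_rate = frameRate(seq),
               injection_index = injectionIndex(seq), detector_max = dmax,
               bits = bits)
  jsonlite::write_json(meta, sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fluorescence sequence written by [writeSequence()]
#'
#' @param path TIFF stack file.
#' @param sidecarPath JSON sidecar (default `<path>.json`); a missing or
#'   inconsistent sidecar is an error.
#' @return a [FluorescenceSequence-class].
#' @export
readSequence <- function(path, sidecarPath = paste0(path, ".json")) {
  if (!file.exists(path))
    stop("stack file not found: ", path, call. = FALSE)
  if (!file.exists(sidecarPath))
    stop("missing sidecar JSON for stack: ", sidecarPath, call. = FALSE)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  need <- c("timestamps", "frame_rate", "injection_index", "detector_max", "bits")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sidecar is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ts <- as.numeric(meta$timestamps)
  if (length(ts) < 1L || ts[1L] <= 0 || any(diff(ts) <= 0))
    stop("sidecar timestamps must be strictly increasing and > 0",
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(ts))
    stop(sprintf("sidecar lists %d timestamps but the stack has %d pages",
                 length(ts), length(pages)), call. = FALSE)
  scale <- 2^meta$bits - 1
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  fr <- array(0, c(H, W, length(pages)))
  for (k in seq_along(pages)) fr[, , k] <- round(pages[[k]] * scale)
  fluorescenceSequence(fr, timestamps = ts, frameRate = meta$frame_rate,
                       injectionIndex = meta$injection_index,
                       detectorMax = meta$detector_max)
}

#' Write a rise-time map as a two-band float TIFF plus JSON sidecar
#'
#' Band 1 holds the rise time scaled by the analysis window into `[0, 1]`
#' (invalid pixels as 0), band 2 the validity mask; the sidecar records
#' the scale. Float storage is 32-bit, so values round-trip to single
#' precision (~1e-7 relative).
#'
#' @param map a [TTPMap-class].
#' @param path output TIFF file.
#' @param sidecarPath output JSON sidecar (default `<path>.json`).
#' @return `path`, invisibly.
#' @export
writeTTPMap <- function(map, path, sidecarPath = paste0(path, ".json")) {
  stopifnot(is(map, "TTPMap"))
  w <- map@window
  b1 <- map@ttp / w
  b1[!map@valid] <- 0
  b2 <- map@valid + 0
  tiff::writeTIFF(list(b1, b2), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(window = w, bands = c("ttp_scaled", "valid")),
                       sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rise-time map written by [writeTTPMap()]
#'
#' Crossing-time bands are not stored; `t25`/`t75` are returned as `NA`
#' with `ttp` and `valid` reconstructed.
#' @param path TIFF file.
#' @param sidecarPath JSON sidecar.
#' @return a [TTPMap-class] (without crossing-time bands).
#' @export
readTTPMap <- function(path, sidecarPath = paste0(path, ".json")) {
  if (!file.exists(sidecarPath))
    stop("missing sidecar JSON for map: ", sidecarPath, call. = FALSE)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  valid <- pages[[2L]] > 0.5
  ttpm <- pages[[1L]] * meta$window
  ttpm[!valid] <- NA_real_
  na <- matrix(NA_real_, nrow(ttpm), ncol(ttpm))
  new("TTPMap", ttp = ttpm, t25 = na, t75 = ttpm * NA, valid = valid,
      window = as.numeric(meta$window))
}

#' Read or write a per-animal records table as CSV
#'
#' Censored lactate readings are stored as the literal string `"Low"`.
#'
#' @param path CSV file.
#' @return [readRecordsCSV()] returns the records data frame.
#' @export
readRecordsCSV <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(lactate = "character"))
  rec$lactate[rec$lactate %in% c("", "NA")] <- NA_character_
  rec$assessment <- as.integer(rec$assessment)
  rec
}

#' @rdname readRecordsCSV
#' @param records records data frame.
#' @return [writeRecordsCSV()] returns `path`, invisibly.
#' @export
writeRecordsCSV <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write ROI masks as a label PNG
#'
#' Labels 0..n are stored in the gray channel as `label/255`, readable by
#' any image viewer and recoverable exactly for up to 255 regions.
#'
#' @param labels integer label matrix.
#' @param path PNG file.
#' @return `path` invisibly, or the label matrix for [readROILabels()].
#' @export
writeROILabels <- function(labels, path) {
  if (max(labels) > 255L) stop("at most 255 ROI labels supported", call. = FALSE)
  png::writePNG(labels / 255, target = path)
  invisible(path)
}

#' @rdname writeROILabels
#' @export
readROILabels <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}
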