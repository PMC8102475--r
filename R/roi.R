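# per-ROI summaries: mean rise time and absolute-intensity extrema

#' Split an ROI label matrix into logical masks
#'
#' @param labels integer label matrix (0 = background).
#' @return named list of logical masks, one per nonzero label.
#' @export
roiMasks <- function(labels) {
  labs <- sort(setdiff(unique(as.vector(labels)), 0L))
  out <- lapply(labs, function(l) labels == l)
  names(out) <- as.character(labs)
  out
}

#' Summarize one region of interest
#'
#' `mean_ttp` is the mean rise time over the ROI's valid map pixels.
#' The absolute-intensity extrema `fi_min` and `fi_max` are the minimum
#' and maximum over time, within the analysis window, of the ROI-averaged
#' intensity trace (single-pixel extrema would be noise-dominated), and
#' `fi_diff = fi_max - fi_min`. At a first injection with no accumulated
#' dye, `fi_min` is the dark pre-arrival level (0 up to noise); with
#' accumulation it rises toward the detector ceiling faster than `fi_max`,
#' so `fi_diff` shrinks.
#'
#' @param map a [TTPMap-class] computed from `seq`.
#' @param seq the [FluorescenceSequence-class] the map came from.
#' @param roi logical mask matrix (or integer matrix of 0/1) selecting the
#'   ROI pixels.
#' @param label optional ROI label used in messages and the output row.
#' @param window analysis window (s) for the intensity extrema.
#' @param minValidFrac below this valid-pixel fraction a warning is
#'   emitted (the ROI mean may be unreliable); zero valid pixels are an
#'   error.
#' @return one-row data frame: `roi`, `n_pixels`, `n_valid`, `mean_ttp`,
#'   `fi_min`, `fi_max`, `fi_diff`.
#' @export
roiStats <- function(map, seq, roi, label = "roi", window = 40,
                     minValidFrac = 0.5) {
  stopifnot(is(map, "TTPMap"), is(seq, "FluorescenceSequence"))
  roi <- roi != 0L
  if (!identical(dim(roi), dim(map)))
    stop(sprintf("ROI '%s': mask dimensions do not match the map", label),
         call. = FALSE)
  n <- sum(roi)
  if (n == 0L)
    stop(sprintf("ROI '%s' is empty", label), call. = FALSE)
  v <- validMask(map) & roi
  nv <- sum(v)
  if (nv == 0L)
    stop(sprintf("ROI '%s' has no valid rise-time pixels", label), call. = FALSE)
  if (nv / n < minValidFrac)
    warning(sprintf("ROI '%s': only %.0f%% of pixels have a valid rise time",
                    label, 100 * nv / n), call. = FALSE)

  ts <- timestamps(seq)
  keep <- which(ts <= window + 1e-9)
  N <- prod(dim(map))
  X <- matrix(seq@frames[, , keep], nrow = N)[as.vector(roi), , drop = FALSE]
  trace <- colMeans(X)

  data.frame(roi = label, n_pixels = n, n_valid = nv,
             mean_ttp = mean(ttp(map)[v]),
             fi_min = min(trace), fi_max = max(trace),
             fi_diff = max(trace) - min(trace),
             stringsAsFactors = FALSE)
}

#' Rise time of the ROI-averaged intensity trace
#'
#' Averages the ROI pixels into a single trace and applies the same
#' normalization/crossing analysis as the per-pixel map. Pixel averaging
#' suppresses detector noise by roughly the square root of the ROI size,
#' so this is the preferred estimator when recovering a region's wash-in
#' time constant (`riseTimeConstant(ttp)`).
#'
#' @inheritParams roiStats
#' @param smoothingWindow,levels as in [computeTTPMap()].
#' @return list with `t25`, `t75`, `ttp` (seconds).
#' @export
roiTraceTTP <- function(seq, roi, window = 40, smoothingWindow = 3L,
                        levels = c(0.25, 0.75)) {
  stopifnot(is(seq, "FluorescenceSequence"))
  roi <- roi != 0L
  d <- dim(seq)
  if (!identical(dim(roi), d[1:2]))
    stop("ROI mask dimensions do not match the sequence", call. = FALSE)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  ts <- timestamps(seq)
  keep <- which(ts <= window + 1e-9)
  X <- matrix(seq@frames[, , keep], nrow = prod(d[1:2]))[as.vector(roi), , drop = FALSE]
  trace <- colMeans(X)
  nt <- normalizeTrace(trace, smoothingWindow)
  if (nt$degenerate) stop("ROI trace is flat; no rise time", call. = FALSE)
  a <- crossingTime(nt$values, ts[keep], levels[1L])
  b <- crossingTime(nt$values, ts[keep], levels[2L])
  list(t25 = a, t75 = b, ttp = b - a)
}

#' Aggregate the four ROI summaries of one assessment
#'
#' Arithmetic means of the per-ROI values. By linearity the mean of the
#' per-ROI `fi_diff` equals the difference of the mean extrema, so only
#' one convention exists.
#'
#' @param stats data frame of exactly four [roiStats()] rows (or a list of
#'   such rows).
#' @param index assessment index 1--5.
#' @return one-row data frame: `assessment`, `mean_ttp`, `fi_min`,
#'   `fi_max`, `fi_diff`.
#' @export
summarizeAssessment <- function(stats, index) {
  if (is.list(stats) && !is.data.frame(stats)) stats <- do.call(rbind, stats)
  if (nrow(stats) != 4L)
    stop(sprintf("expected exactly 4 ROI summaries, got %d", nrow(stats)),
         call. = FALSE)
  data.frame(assessment = as.integer(index),
             mean_ttp = mean(stats$mean_ttp),
             fi_min = mean(stats$fi_min),
             fi_max = mean(stats$fi_max),
             fi_diff = mean(stats$fi_diff))
}
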