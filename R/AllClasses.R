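#' Kinetic parameters of a pixel-wise ICG wash-in curve
#'
#' The noiseless fluorescence trace of a perfused region is modelled as
#' \deqn{I(t) = B + A \, S((t - t_0)/\tau)}
#' where \eqn{S} is the standard logistic function. `t0` is the dye arrival
#' (inflection) time in seconds, `tau` the rise time constant in seconds
#' (the 25--75% rise time of a logistic is \eqn{2\ln(3)\tau}), `A` the
#' wash-in amplitude and `B` the pre-injection baseline in detector units
#' (residual dye accumulated from earlier injections), and `sigma` the
#' standard deviation of additive Gaussian detector noise.
#'
#' @slot t0 arrival time (s), `>= 0`
#' @slot tau rise time constant (s), `> 0`
#' @slot A wash-in amplitude (detector units), `>= 0`
#' @slot B baseline (detector units), `>= 0`
#' @slot sigma noise standard deviation (detector units), `>= 0`
#' @seealso [kineticParams()], [accumulateBaseline()], [simulateSequence()]
#' @exportClass KineticParams
setClass("KineticParams",
  representation(t0 = "numeric", tau = "numeric", A = "numeric",
                 B = "numeric", sigma = "numeric"))

setValidity("KineticParams", function(object) {
  msg <- character()
  scal <- function(x) length(x) == 1L && is.finite(x)
  if (!scal(object@t0) || object@t0 < 0) msg <- c(msg, "t0 must be a finite scalar >= 0")
  if (!scal(object@tau) || object@tau <= 0) msg <- c(msg, "tau must be a finite scalar > 0")
  if (!scal(object@A) || object@A < 0) msg <- c(msg, "A must be a finite scalar >= 0")
  if (!scal(object@B) || object@B < 0) msg <- c(msg, "B must be a finite scalar >= 0")
  if (!scal(object@sigma) || object@sigma < 0) msg <- c(msg, "sigma must be a finite scalar >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct kinetic parameters for a wash-in curve
#'
#' @param t0 arrival (inflection) time in seconds.
#' @param tau rise time constant in seconds.
#' @param A wash-in amplitude in detector units.
#' @param B baseline (accumulated dye) in detector units.
#' @param sigma additive Gaussian noise SD in detector units.
#' @return A [KineticParams-class] object.
#' @examples
#' kp <- kineticParams(t0 = 10, tau = 2, A = 100)
#' riseTime(kp)   # 2 * log(3) * 2 = 4.39 s
#' @export
kineticParams <- function(t0, tau, A, B = 0, sigma = 0) {
  new("KineticParams", t0 = as.numeric(t0), tau = as.numeric(tau),
      A = as.numeric(A), B = as.numeric(B), sigma = as.numeric(sigma))
}

#' A timestamped fluorescence image stack from one ICG injection
#'
#' Frames are stored as an `H x W x T` array of grayscale intensities in
#' detector units on a fixed range `[0, detectorMax]`. Timestamps are
#' seconds since the ICG injection (the time origin), strictly increasing
#' and strictly positive.
#'
#' @slot frames numeric `H x W x T` array.
#' @slot timestamps numeric vector of length `T`, strictly increasing, `> 0`.
#' @slot frameRate acquisition rate in Hz.
#' @slot injectionIndex which of the repeated injections (1--5) this stack
#'   belongs to.
#' @slot detectorMax upper end of the detector range.
#' @seealso [simulateSequence()], [computeTTPMap()], [writeSequence()]
#' @exportClass FluorescenceSequence
setClass("FluorescenceSequence",
  representation(frames = "array", timestamps = "numeric",
                 frameRate = "numeric", injectionIndex = "integer",
                 detectorMax = "numeric"))

setValidity("FluorescenceSequence", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be an H x W x T array")
  else {
    if (length(object@timestamps) != d[3L])
      msg <- c(msg, "timestamps length must equal the number of frames")
    if (any(!is.finite(object@frames)))
      msg <- c(msg, "intensities must be finite")
    else if (min(object@frames) < 0 || max(object@frames) > object@detectorMax)
      msg <- c(msg, "intensities must lie within [0, detectorMax]")
  }
  if (length(object@timestamps)) {
    if (object@timestamps[1L] <= 0)
      msg <- c(msg, "first timestamp must be > 0 s (time origin is the injection)")
    if (any(diff(object@timestamps) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a positive scalar")
  if (length(object@injectionIndex) != 1L || is.na(object@injectionIndex) ||
      object@injectionIndex < 1L || object@injectionIndex > 5L)
    msg <- c(msg, "injectionIndex must be in 1..5")
  if (length(object@detectorMax) != 1L || !is.finite(object@detectorMax) || object@detectorMax <= 0)
    msg <- c(msg, "detectorMax must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a fluorescence sequence from a frame array
#'
#' @param frames numeric `H x W x T` array of intensities.
#' @param timestamps seconds since injection for each frame.
#' @param frameRate acquisition rate (Hz); defaults to the reciprocal
#'   median frame spacing.
#' @param injectionIndex injection number (1--5).
#' @param detectorMax detector ceiling (default 255, 8-bit convention).
#' @return A [FluorescenceSequence-class].
#' @export
fluorescenceSequence <- function(frames, timestamps, frameRate = NULL,
                                 injectionIndex = 1L, detectorMax = 255) {
  if (is.null(frameRate)) {
    dt <- diff(timestamps)
    frameRate <- 1 / stats::median(dt)
  }
  new("FluorescenceSequence", frames = frames,
      timestamps = as.numeric(timestamps), frameRate = as.numeric(frameRate),
      injectionIndex = as.integer(injectionIndex),
      detectorMax = as.numeric(detectorMax))
}

#' Per-pixel 25--75% rise-time (TTP) map
#'
#' `ttp[i, j] = t75[i, j] - t25[i, j]` wherever `valid[i, j]` is `TRUE`.
#' Pixels with a degenerate (flat) trace, or whose normalized trace never
#' reaches the upper threshold inside the analysis window, are invalid and
#' carry `NA` in all numeric bands.
#'
#' @slot ttp numeric `H x W` matrix of rise times (s).
#' @slot t25,t75 numeric `H x W` matrices of the threshold crossing times (s).
#' @slot valid logical `H x W` validity mask.
#' @slot window analysis window (s) the map was computed on.
#' @seealso [computeTTPMap()], [roiStats()], [renderCartography()]
#' @exportClass TTPMap
setClass("TTPMap",
  representation(ttp = "matrix", t25 = "matrix", t75 = "matrix",
                 valid = "matrix", window = "numeric"))

setValidity("TTPMap", function(object) {
  msg <- character()
  d <- dim(object@ttp)
  if (!identical(dim(object@t25), d) || !identical(dim(object@t75), d) ||
      !identical(dim(object@valid), d))
    msg <- c(msg, "ttp, t25, t75 and valid must share dimensions")
  if (!is.logical(object@valid)) msg <- c(msg, "valid must be a logical matrix")
  else {
    v <- object@valid & !is.na(object@valid)
    if (any(v)) {
      bad <- abs(object@ttp[v] - (object@t75[v] - object@t25[v])) > 1e-9
      if (any(bad, na.rm = TRUE)) msg <- c(msg, "ttp must equal t75 - t25 where valid")
      if (any(object@ttp[v] < 0, na.rm = TRUE)) msg <- c(msg, "ttp must be >= 0 where valid")
    }
  }
  if (length(msg)) msg else TRUE
})

#' FLER perfusion cartography overlay
#'
#' An RGBA overlay image mapping rise times through a colormap between
#' fixed normalization bounds. Invalid pixels are fully transparent, so
#' alpha-blending onto a background frame leaves them untouched.
#'
#' @slot rgba numeric `H x W x 4` array in `[0, 1]`.
#' @slot bounds length-2 numeric, the `(ttp_lo, ttp_hi)` normalization range (s).
#' @slot colormap name of the palette used (a `grDevices::hcl.colors` palette).
#' @seealso [renderCartography()], [blendCartography()]
#' @exportClass Cartography
setClass("Cartography",
  representation(rgba = "array", bounds = "numeric", colormap = "character"))

setValidity("Cartography", function(object) {
  msg <- character()
  d <- dim(object@rgba)
  if (length(d) != 3L || d[3L] != 4L) msg <- c(msg, "rgba must be an H x W x 4 array")
  else if (min(object@rgba) < 0 || max(object@rgba) > 1)
    msg <- c(msg, "rgba values must lie in [0, 1]")
  if (length(object@bounds) != 2L || any(!is.finite(object@bounds)) ||
      object@bounds[1L] >= object@bounds[2L])
    msg <- c(msg, "bounds must be finite with ttp_lo < ttp_hi")
  if (length(msg)) msg else TRUE
})
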