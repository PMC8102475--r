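# generics, accessors and show methods

#' @describeIn FluorescenceSequence-class frame array accessor
#' @param object,x a `FluorescenceSequence`
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @export
setMethod("frames", "FluorescenceSequence", function(object) object@frames)

#' @describeIn FluorescenceSequence-class timestamps (s since injection)
#' @export
setGeneric("timestamps", function(object) standardGeneric("timestamps"))
#' @export
setMethod("timestamps", "FluorescenceSequence", function(object) object@timestamps)

#' @describeIn FluorescenceSequence-class acquisition rate (Hz)
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @export
setMethod("frameRate", "FluorescenceSequence", function(object) object@frameRate)

#' @describeIn FluorescenceSequence-class injection number (1--5)
#' @export
setGeneric("injectionIndex", function(object) standardGeneric("injectionIndex"))
#' @export
setMethod("injectionIndex", "FluorescenceSequence", function(object) object@injectionIndex)

#' @describeIn FluorescenceSequence-class detector ceiling
#' @export
setGeneric("detectorMax", function(object) standardGeneric("detectorMax"))
#' @export
setMethod("detectorMax", "FluorescenceSequence", function(object) object@detectorMax)

#' @export
setMethod("dim", "FluorescenceSequence", function(x) dim(x@frames))

setMethod("show", "FluorescenceSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FluorescenceSequence: %d x %d pixels, %d frames @ %.3g Hz\n", d[1L],
    d[2L], d[3L], object@frameRate))
  cat(sprintf("  injection %d; t in (%.2f, %.2f] s; detector range [0, %g]\n",
              object@injectionIndex, object@timestamps[1L],
              object@timestamps[d[3L]], object@detectorMax))
})

#' @describeIn TTPMap-class rise-time matrix (s; `NA` where invalid)
#' @param object,x a `TTPMap`
#' @export
setGeneric("ttp", function(object) standardGeneric("ttp"))
#' @export
setMethod("ttp", "TTPMap", function(object) object@ttp)

#' @describeIn TTPMap-class logical validity mask
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @export
setMethod("validMask", "TTPMap", function(object) object@valid)

#' @describeIn TTPMap-class lower-threshold crossing times (s)
#' @export
setGeneric("t25", function(object) standardGeneric("t25"))
#' @export
setMethod("t25", "TTPMap", function(object) object@t25)

#' @describeIn TTPMap-class upper-threshold crossing times (s)
#' @export
setGeneric("t75", function(object) standardGeneric("t75"))
#' @export
setMethod("t75", "TTPMap", function(object) object@t75)

#' @export
setMethod("dim", "TTPMap", function(x) dim(x@ttp))

setMethod("show", "TTPMap", function(object) {
  nv <- sum(object@valid)
  cat(sprintf("TTPMap: %d x %d pixels, %d valid (%.1f%%), window %g s\n",
              nrow(object@ttp), ncol(object@ttp), nv,
              100 * nv / length(object@valid), object@window))
  if (nv) cat(sprintf("  ttp: median %.2f s, range [%.2f, %.2f] s\n",
                      stats::median(object@ttp[object@valid]),
                      min(object@ttp[object@valid]), max(object@ttp[object@valid])))
})

#' @describeIn Cartography-class RGBA overlay array accessor
#' @param object a `Cartography`
#' @export
setGeneric("overlayArray", function(object) standardGeneric("overlayArray"))
#' @export
setMethod("overlayArray", "Cartography", function(object) object@rgba)

#' @describeIn Cartography-class `(ttp_lo, ttp_hi)` normalization bounds (s)
#' @export
setGeneric("ttpBounds", function(object) standardGeneric("ttpBounds"))
#' @export
setMethod("ttpBounds", "Cartography", function(object) object@bounds)

setMethod("show", "Cartography", function(object) {
  d <- dim(object@rgba)
  cat(sprintf("Cartography: %d x %d, colormap '%s', bounds [%.2f, %.2f] s\n",
              d[1L], d[2L], object@colormap, object@bounds[1L], object@bounds[2L]))
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf(
    "KineticParams: t0 = %g s, tau = %g s, A = %g, B = %g, sigma = %g\n",
    object@t0, object@tau, object@A, object@B, object@sigma))
})

#' Analytic 25--75% rise time of a logistic wash-in
#'
#' For a logistic wash-in with time constant `tau`, the elapsed time between
#' the 25% and 75% crossings of the asymptotic range is `2 * log(3) * tau`.
#' Given a measured rise time, `riseTimeConstant()` inverts the relation.
#'
#' @param object a [KineticParams-class] (or a numeric `tau`).
#' @return rise time in seconds.
#' @export
setGeneric("riseTime", function(object) standardGeneric("riseTime"))
#' @export
setMethod("riseTime", "KineticParams", function(object) 2 * log(3) * object@tau)
#' @export
setMethod("riseTime", "numeric", function(object) 2 * log(3) * object)

#' @rdname riseTime
#' @param ttp measured 25--75% rise time in seconds.
#' @export
riseTimeConstant <- function(ttp) ttp / (2 * log(3))
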