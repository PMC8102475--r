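# wash-in kinetics and detector model

#' Evaluate a noiseless wash-in trace
#'
#' Returns `B + A * S((t - t0)/tau)` with `S` the standard logistic
#' function, i.e. the ideal (pre-detector) fluorescence trace of a pixel
#' with the given kinetic parameters. An optional gamma-variate family is
#' provided as an alternative bolus shape; the logistic is the default
#' because its 25--75% rise time has the closed form `2 * log(3) * tau`.
#'
#' @param t numeric vector of times (s since injection).
#' @param params a [KineticParams-class].
#' @param family `"logistic"` (default) or `"gamma"`. The gamma-variate
#'   uses shape 3 with scale `tau`, onset at `t0 - 3 * tau` (peak near `t0`),
#'   normalized to amplitude `A`; it rises and then decays.
#' @return numeric vector of intensities (detector units, pre-noise).
#' @examples
#' washInTrace(5, kineticParams(t0 = 5, tau = 2, A = 100))  # logistic midpoint: 50
#' @export
washInTrace <- function(t, params, family = c("logistic", "gamma")) {
  stopifnot(is(params, "KineticParams"))
  family <- match.arg(family)
  if (family == "logistic") {
    params@B + params@A * plogis((t - params@t0) / params@tau)
  } else {
    k <- 3
    onset <- params@t0 - k * params@tau
    x <- pmax(t - onset, 0) / params@tau
    # gamma-variate x^k * exp(-x), unit-normalized at its mode x = k
    params@B + params@A * (x / k)^k * exp(k - x)
  }
}

#' Detector transfer function
#'
#' Maps ideal fluorescence to recorded intensity. `"linear"` applies a hard
#' clip to `[0, ceiling]` only. `"saturating"` applies the smooth compressor
#' \deqn{f(x) = c\,(1 - e^{-x/c})}
#' (a Beer--Lambert-like saturation with ceiling `c`) followed by the same
#' clip. Under the saturating response, an accumulated baseline `B` scales
#' the recorded wash-in amplitude by `exp(-B/c)` but cancels exactly from
#' the min--max normalized trace, which is what makes rise-time mapping
#' robust to dye accumulation while absolute intensities saturate.
#'
#' @param x ideal intensity (detector units).
#' @param response `"linear"` or `"saturating"`.
#' @param ceiling detector ceiling (default 255).
#' @return recorded intensity in `[0, ceiling]`.
#' @export
detectorResponse <- function(x, response = c("linear", "saturating"),
                             ceiling = 255) {
  response <- match.arg(response)
  if (response == "saturating") x <- ceiling * (1 - exp(-x / ceiling))
  clamp(x, 0, ceiling)
}

#' Carry accumulated dye into the next injection's baseline
#'
#' After an injection with amplitude `A`, a fraction `retention` of the dye
#' remains in the tissue at the next assessment, raising its baseline:
#' `B' = B + retention * A`. All other kinetic parameters are preserved.
#' Chained over `k` injections with constant `A` this gives
#' `B_k = A * retention * (k - 1)`.
#'
#' @param prev [KineticParams-class] of the previous injection.
#' @param retention fraction of the amplitude retained, in `[0, 1]`.
#' @return [KineticParams-class] for the next injection.
#' @export
accumulateBaseline <- function(prev, retention) {
  stopifnot(is(prev, "KineticParams"))
  if (!is.numeric(retention) || length(retention) != 1L || is.na(retention) ||
      retention < 0 || retention > 1)
    stop("'retention' must be a single value in [0, 1]", call. = FALSE)
  prev@B <- prev@B + retention * prev@A
  validObject(prev)
  prev
}
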