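# independent oracles used across the suite

# 25-75% crossing gap of a min-max-normalized logistic, computed on a
# dense numeric grid with stats::approx inversion -- independent of the
# package's crossing code.
denseLogisticGap <- function(t0, tau, tmax = 40, n = 2e5,
                             levels = c(0.25, 0.75)) {
  t <- seq(tmax / n, tmax, length.out = n)
  y <- stats::plogis((t - t0) / tau)
  y <- (y - min(y)) / (max(y) - min(y))
  cross <- function(l) {
    j <- which(y >= l)[1L]
    stats::approx(y[(j - 1L):j], t[(j - 1L):j], xout = l)$y
  }
  cross(levels[2L]) - cross(levels[1L])
}

# two-sided Student-t p-value by numeric integration of the explicit
# density -- independent of stats::pt
tOracleP <- function(tstat, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
}

# uniform single-region stack: every pixel shares one kinetic parameter set
uniformSequence <- function(t0, tau, A, B = 0, sigma = 0, dims = c(8, 8),
                            seed = 1, quantize = FALSE, duration = 40,
                            frameRate = 10, detector = "linear",
                            detectorMax = 255) {
  simulateSequence(list("1" = kineticParams(t0, tau, A, B, sigma)),
                   matrix(1L, dims[1L], dims[2L]), duration = duration,
                   frameRate = frameRate, seed = seed, detector = detector,
                   detectorMax = detectorMax, quantize = quantize)
}
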