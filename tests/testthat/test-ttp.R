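# trace normalization, threshold crossing, rise-time maps

test_that("min-max normalization is affine and flags flat traces", {
  n <- normalizeTrace(c(10, 20, 30))
  expect_equal(n$values, c(0, 0.5, 1))
  expect_false(n$degenerate)
  expect_true(normalizeTrace(c(7, 7, 7))$degenerate)

  x <- c(3, 9, 4, 20, 18)
  for (gain in c(0.5, 2)) for (offset in c(0, 11))
    expect_equal(normalizeTrace(gain * x + offset)$values,
                 normalizeTrace(x)$values)
  expect_error(normalizeTrace(5), "2 frames")
})

test_that("crossing times interpolate linearly and signal unreached levels", {
  tm <- 0:10
  ramp <- seq(0, 1, 0.1)
  expect_equal(crossingTime(ramp, tm, 0.25), 2.5)
  expect_equal(crossingTime(ramp, tm, 0.75), 7.5)

  # step between 4 and 5 s: both crossings inside the step interval
  step <- c(rep(0, 5), rep(1, 6))
  a <- crossingTime(step, tm, 0.25); b <- crossingTime(step, tm, 0.75)
  expect_true(a > 4 && b < 5 && b - a < 1)

  expect_identical(crossingTime(c(0, 0.4, 0.5), 0:2, 0.9), NA_real_)
  expect_error(crossingTime(ramp, tm, 1.2), "level")
  # earliest-crossing rule on a non-monotone trace
  wob <- c(0, 0.6, 0.2, 0.8, 1)
  expect_lt(crossingTime(wob, 0:4, 0.5), 1)
})

test_that("rise-time maps match the logistic oracle on uniform fields", {
  s <- uniformSequence(t0 = 12, tau = 2, A = 100, dims = c(16, 16))
  m <- computeTTPMap(s, smoothingWindow = 1)
  expect_true(all(validMask(m)))
  expect_equal(mean(ttp(m)), 2 * log(3) * 2, tolerance = 0.1 / (2 * log(3) * 2))
  expect_equal(ttp(m), t75(m) - t25(m))
  # dense numeric oracle agrees with the analytic closed form here
  expect_equal(denseLogisticGap(12, 2), 2 * log(3) * 2, tolerance = 0.01)
})

test_that("flat regions are invalid, not assigned a sentinel", {
  s <- uniformSequence(t0 = 10, tau = 2, A = 0, B = 40, dims = c(6, 6))
  m <- computeTTPMap(s)
  expect_false(any(validMask(m)))
  expect_true(all(is.na(ttp(m))))
})

test_that("maps are invariant to gain and baseline shifts", {
  s <- uniformSequence(t0 = 10, tau = 1.5, A = 100, dims = c(12, 12),
                       sigma = 3, seed = 4)
  m <- computeTTPMap(s)
  tr <- fluorescenceSequence(1.7 * frames(s) + 20, timestamps(s),
                             frameRate(s), detectorMax = 1000)
  m2 <- computeTTPMap(tr)
  expect_identical(validMask(m), validMask(m2))
  expect_equal(ttp(m), ttp(m2), tolerance = 1e-9)
})

test_that("rise time is strictly increasing in the time constant", {
  taus <- c(0.5, 1, 1.5, 2, 3)
  vals <- sapply(taus, function(tau) {
    s <- uniformSequence(t0 = 12, tau = tau, A = 100, dims = c(3, 3))
    mean(ttp(computeTTPMap(s, smoothingWindow = 1)))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("short sequences and bad thresholds are rejected", {
  s <- uniformSequence(10, 2, 100, dims = c(3, 3))
  short <- fluorescenceSequence(frames(s)[, , 1:100, drop = FALSE],
                                timestamps(s)[1:100], frameRate(s))
  expect_error(computeTTPMap(short), "analysis window")
  expect_error(computeTTPMap(s, levels = c(0.75, 0.25)), "increasing")
  expect_error(computeTTPMap(s, levels = c(0, 0.75)), "increasing|\\(0, 1\\)")
})

test_that("accumulation leaves the normalized trace unchanged under saturation", {
  # exponential-compressor detector: baseline factors out of min-max shape
  tm <- seq(0.1, 40, 0.1)
  for (B in c(0, 80, 200)) {
    y <- detectorResponse(washInTrace(tm, kineticParams(10, 2, 100, B = B)),
                          "saturating")
    n <- normalizeTrace(y)
    if (B == 0) ref <- n$values
    expect_equal(n$values, ref, tolerance = 1e-10)
  }
})
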