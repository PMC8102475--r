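# wash-in kinetics, detector model, baseline accumulation

test_that("logistic wash-in hits its midpoint and closed-form rise time", {
  kp <- kineticParams(t0 = 5, tau = 2, A = 100)
  expect_equal(washInTrace(5, kp), 50)
  expect_equal(washInTrace(c(-1e6, 1e6), kp), c(0, 100), tolerance = 1e-12)

  # 25->75% crossing gap of the pure logistic: solve S(x) = l analytically
  x25 <- 2 * log(0.25 / 0.75)   # tau * logit(l), tau = 2
  x75 <- 2 * log(0.75 / 0.25)
  expect_equal(x75 - x25, 2 * log(3) * 2)
  expect_equal(riseTime(kp), 2 * log(3) * 2)
  # dense-grid numeric confirmation (window-truncation bias is tiny here)
  expect_equal(denseLogisticGap(t0 = 12, tau = 2), 2 * log(3) * 2,
               tolerance = 0.01)
})

test_that("zero-amplitude kinetics give a flat trace at the baseline", {
  kp <- kineticParams(t0 = 5, tau = 2, A = 0, B = 17)
  expect_equal(washInTrace(seq(0, 40, 0.5), kp), rep(17, 81))
})

test_that("adding baseline shifts the ideal trace by exactly that constant", {
  t <- seq(0.1, 40, 0.1)
  a <- washInTrace(t, kineticParams(8, 1.5, 90, B = 0))
  b <- washInTrace(t, kineticParams(8, 1.5, 90, B = 33.25))
  expect_equal(b - a, rep(33.25, length(t)))
})

test_that("noiseless traces are monotone non-decreasing", {
  t <- seq(0.1, 40, 0.1)
  for (tau in c(0.5, 2, 5)) {
    y <- washInTrace(t, kineticParams(10, tau, 120, B = 5))
    expect_true(all(diff(y) >= 0))
    # and through the saturating detector (monotone transform)
    expect_true(all(diff(detectorResponse(y, "saturating")) >= 0))
  }
})

test_that("detector response saturates smoothly and clips hard", {
  expect_equal(detectorResponse(c(-5, 0, 300), "linear"), c(0, 0, 255))
  x <- c(0, 50, 200, 1000)
  y <- detectorResponse(x, "saturating")
  expect_equal(y, pmin(255 * (1 - exp(-x / 255)), 255))
  expect_true(all(diff(y) > 0))
  expect_lt(max(y), 255)
})

test_that("baseline accumulation follows B' = B + retention * A", {
  kp <- kineticParams(5, 2, A = 100, B = 0)
  expect_equal(accumulateBaseline(kp, 0.6)@B, 60)
  expect_equal(accumulateBaseline(kp, 0)@B, 0)         # identity
  expect_error(accumulateBaseline(kp, 1.2), "retention")
  expect_error(accumulateBaseline(kp, -0.1), "retention")

  # chained: B at injection k equals A * r * (k - 1) for constant A
  r <- 0.37
  p <- kp
  for (k in 1:5) {
    expect_equal(p@B, 100 * r * (k - 1))
    p <- accumulateBaseline(p, r)
  }
})

test_that("kinetic parameter validity is enforced", {
  expect_error(kineticParams(-1, 2, 100), "t0")
  expect_error(kineticParams(5, 0, 100), "tau")
  expect_error(kineticParams(5, 2, -3), "A")
  expect_error(kineticParams(5, 2, 100, sigma = -1), "sigma")
})
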