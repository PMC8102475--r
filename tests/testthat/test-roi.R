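# per-ROI summaries

makeTwoRegionSeq <- function(dims = c(12, 12), tauB = 4) {
  labels <- matrix(0L, dims[1], dims[2])
  labels[2:5, 2:5] <- 1L
  labels[8:11, 8:11] <- 2L
  s <- simulateSequence(list("1" = kineticParams(12, 2, 100),
                             "2" = kineticParams(12, tauB, 100)),
                        labels, seed = 3, quantize = FALSE)
  list(seq = s, labels = labels)
}

test_that("uniform fields give every ROI the oracle mean rise time", {
  labels <- squareROILayout(c(16, 16), n = 4, size = 4)
  s <- simulateSequence(list("1" = kineticParams(12, 2, 100),
                             "2" = kineticParams(12, 2, 100),
                             "3" = kineticParams(12, 2, 100),
                             "4" = kineticParams(12, 2, 100)),
                        labels, seed = 2, quantize = FALSE)
  map <- computeTTPMap(s, smoothingWindow = 1)
  for (m in roiMasks(labels)) {
    rs <- roiStats(map, s, m)
    expect_equal(rs$mean_ttp, 2 * log(3) * 2, tolerance = 0.1)
    expect_equal(rs$n_valid, 16)
  }
})

test_that("intensity extrema read the ROI-averaged trace in the window", {
  # first injection, no accumulated dye: pre-arrival level is dark
  s1 <- uniformSequence(t0 = 10, tau = 1, A = 100, dims = c(6, 6))
  map1 <- computeTTPMap(s1)
  roi <- matrix(TRUE, 6, 6)
  rs1 <- roiStats(map1, s1, roi)
  expect_equal(rs1$fi_min, 0, tolerance = 0.01)
  expect_equal(rs1$fi_max, 100, tolerance = 0.01)

  # after accumulation with retention 0.6 the floor is the new baseline
  kp <- accumulateBaseline(kineticParams(10, 1, 100), 0.6)
  s2 <- simulateSequence(list("1" = kp), matrix(1L, 6, 6), seed = 1,
                         quantize = FALSE)
  rs2 <- roiStats(computeTTPMap(s2), s2, roi)
  expect_equal(rs2$fi_min, 60, tolerance = 0.01)
  expect_equal(rs2$fi_diff, rs2$fi_max - rs2$fi_min)
})

test_that("extrema ignore frames beyond the analysis window", {
  s40 <- uniformSequence(10, 2, 100, duration = 40)
  s50 <- uniformSequence(10, 2, 100, duration = 50)
  roi <- matrix(TRUE, 8, 8)
  a <- roiStats(computeTTPMap(s40), s40, roi)
  b <- roiStats(computeTTPMap(s50), s50, roi)
  expect_equal(a[, -1], b[, -1])
})

test_that("empty, mismatched and all-invalid ROIs are errors; sparse valid warns", {
  s <- uniformSequence(10, 2, 100, dims = c(8, 8))
  map <- computeTTPMap(s)
  expect_error(roiStats(map, s, matrix(FALSE, 8, 8), label = "r1"),
               "'r1' is empty")
  expect_error(roiStats(map, s, matrix(TRUE, 4, 4)), "dimensions")

  labels <- matrix(0L, 10, 10)
  labels[1:5, ] <- 1L            # perfused rows
  s2 <- simulateSequence(list("1" = kineticParams(10, 2, 100),
                              "0" = kineticParams(0, 1, 0)),
                         labels, seed = 1, quantize = FALSE)
  map2 <- computeTTPMap(s2)
  expect_error(roiStats(map2, s2, labels == 0, label = "bg"),
               "no valid rise-time pixels")
  # ROI 40% perfused / 60% flat: usable but flagged
  roi <- matrix(FALSE, 10, 10); roi[4:8, 1:4] <- TRUE
  expect_warning(roiStats(map2, s2, roi, label = "mix"), "valid rise time")
})

test_that("assessment summaries are means with exact diff linearity", {
  x <- makeTwoRegionSeq()
  map <- computeTTPMap(x$seq, smoothingWindow = 1)
  masks <- list(x$labels == 1, x$labels == 2)
  rs <- rbind(roiStats(map, x$seq, masks[[1]], label = "1"),
              roiStats(map, x$seq, masks[[2]], label = "2"),
              roiStats(map, x$seq, masks[[1]], label = "3"),
              roiStats(map, x$seq, masks[[2]], label = "4"))
  sm <- summarizeAssessment(rs, 1)
  expect_equal(sm$mean_ttp, mean(rs$mean_ttp))
  # linearity: mean of per-ROI diffs == diff of means
  expect_equal(sm$fi_diff, sm$fi_max - sm$fi_min)

  # permuting ROI order changes nothing
  sm2 <- summarizeAssessment(rs[c(3, 1, 4, 2), ], 1)
  expect_equal(sm2, sm)

  # four identical ROIs reduce to the single ROI row
  rs4 <- rs[c(1, 1, 1, 1), ]
  sm4 <- summarizeAssessment(rs4, 2)
  expect_equal(sm4$mean_ttp, rs$mean_ttp[1])
  expect_equal(sm4$fi_diff, rs$fi_diff[1])

  expect_error(summarizeAssessment(rs[1:3, ], 1), "exactly 4")
})

test_that("ROI-trace rise time recovers each region's time constant", {
  x <- makeTwoRegionSeq(tauB = 4)
  tt1 <- roiTraceTTP(x$seq, x$labels == 1, smoothingWindow = 1)
  expect_equal(riseTimeConstant(tt1$ttp), 2, tolerance = 0.02)
  tt2 <- roiTraceTTP(x$seq, x$labels == 2, smoothingWindow = 1)
  expect_gt(tt2$ttp, tt1$ttp)
})
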