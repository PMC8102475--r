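# synthetic videography generator

test_that("noiseless sequences sample the kinetic model exactly", {
  s <- uniformSequence(t0 = 5, tau = 2, A = 100, dims = c(4, 4))
  # logistic midpoint: frame at t = 5 s reads 50
  k <- which(abs(timestamps(s) - 5) < 1e-9)
  expect_equal(unname(frames(s)[2, 3, k]), 50)
  # zero amplitude: every frame identical to the baseline
  s0 <- uniformSequence(t0 = 5, tau = 2, A = 0, B = 12.5, dims = c(4, 4))
  expect_true(all(frames(s0) == 12.5))
})

test_that("sequence validity invariants hold and violations are caught", {
  s <- uniformSequence(10, 2, 100, sigma = 3, seed = 9, quantize = TRUE)
  expect_equal(length(timestamps(s)), dim(s)[3])
  expect_gt(timestamps(s)[1], 0)
  expect_true(all(diff(timestamps(s)) > 0))
  expect_true(min(frames(s)) >= 0 && max(frames(s)) <= 255)
  expect_true(all(frames(s) == round(frames(s))))

  expect_error(fluorescenceSequence(array(0, c(2, 2, 3)), c(0, 1, 2)),
               "timestamp")
  expect_error(fluorescenceSequence(array(0, c(2, 2, 3)), c(1, 3, 2)),
               "increasing")
  expect_error(fluorescenceSequence(array(300, c(2, 2, 2)), c(1, 2)),
               "detectorMax")
})

test_that("short recordings and overlapping regions are rejected", {
  pm <- list("1" = kineticParams(5, 1, 50))
  expect_error(
    simulateSequence(pm, matrix(1L, 4, 4), duration = 30, seed = 1),
    "40-s analysis window")
  m1 <- matrix(FALSE, 4, 4); m1[1:2, ] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[2:3, ] <- TRUE
  expect_error(
    simulateSequence(list("1" = kineticParams(5, 1, 50),
                          "2" = kineticParams(5, 1, 50)),
                     list(m1, m2), seed = 1),
    "overlap")
  # disjoint masks are accepted
  m2b <- matrix(FALSE, 4, 4); m2b[3:4, ] <- TRUE
  expect_s4_class(
    simulateSequence(list("1" = kineticParams(10, 1, 50),
                          "2" = kineticParams(10, 1, 50)),
                     list(m1, m2b), seed = 1),
    "FluorescenceSequence")
})

test_that("simulation is deterministic given a seed and leaves the RNG alone", {
  set.seed(123); before <- runif(1)
  a <- uniformSequence(10, 2, 100, sigma = 4, seed = 77, quantize = TRUE)
  b <- uniformSequence(10, 2, 100, sigma = 4, seed = 77, quantize = TRUE)
  expect_identical(frames(a), frames(b))
  c <- uniformSequence(10, 2, 100, sigma = 4, seed = 78, quantize = TRUE)
  expect_false(identical(frames(a), frames(c)))
  set.seed(123); expect_identical(before, runif(1))
})

test_that("the protocol simulator matches the study structure", {
  sc <- protocolScenario(dims = c(24, 24), roiSize = 6L)
  p <- simulateProtocol(3, seed = 11, scenario = sc)
  expect_length(p$sequences, 3)
  expect_true(all(lengths(p$sequences) == 5))
  expect_identical(sort(unique(p$records$assessment)), 1:5)
  validateAnimalRecords(p$records)

  # ICG dose rule: 0.1 mg/kg rounded to one decimal
  w <- unique(p$records[, c("weight_kg", "icg_dose_mg")])
  expect_equal(w$icg_dose_mg, round(w$weight_kg / 10, 1))

  # hemodynamic collapse at the remnant assessment
  for (id in unique(p$records$animal_id)) {
    r <- p$records[p$records$animal_id == id, ]
    expect_lt(r$systolic[r$assessment %in% 5],
              r$systolic[r$assessment %in% 4])
  }
  expect_error(simulateProtocol(0, seed = 1), "at least 1")
})

test_that("two protocol runs with one seed are bitwise identical", {
  sc <- protocolScenario(dims = c(16, 16), roiSize = 4L)
  p1 <- simulateProtocol(2, seed = 5, scenario = sc)
  p2 <- simulateProtocol(2, seed = 5, scenario = sc)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$kinetics, p2$kinetics)
  expect_identical(frames(p1$sequences[[2]][[4]]), frames(p2$sequences[[2]][[4]]))
})

test_that("mean minimum ROI intensity is non-decreasing across injections", {
  sc <- protocolScenario(dims = c(24, 24), roiSize = 6L)
  p <- simulateProtocol(1, seed = 31, scenario = sc)
  masks <- roiMasks(p$roiLayout)
  fmin <- sapply(1:5, function(k) {
    s <- p$sequences[[1]][[k]]
    map <- computeTTPMap(s)
    mean(sapply(names(masks), function(r)
      roiStats(map, s, masks[[r]], label = r)$fi_min))
  })
  expect_true(all(diff(fmin) >= 0))
})
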