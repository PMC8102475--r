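# synthetic videography: sequences and full study protocols

# Published per-time-point hemodynamic moments (mean, SD across the five
# pigs) used to bracket the uniform sampling ranges of the simulator.
.hemodynamicMoments <- function() {
  data.frame(
    timepoint_min = c(0, 10, 25, 35, 50, 60, 75, 85),
    assessment    = c(1L, NA, 2L, NA, 3L, NA, 4L, 5L),
    ne_dose       = c(0, 0, 0.1, 0.1, 0.5, 0.5, 1.0, 1.0),
    hr_mean  = c(86, 82, 88, 89, 109, 110, 129, 108),
    hr_sd    = c(14, 13, 9, 9, 16, 15, 23, 19),
    sys_mean = c(62, 55, 84, 78, 117, 96, 119, 39),
    sys_sd   = c(14, 12, 10, 13, 33, 33, 21, 8),
    dia_mean = c(36, 34, 52, 46, 71, 54, 66, 25),
    dia_sd   = c(8, 6, 9, 9, 26, 16, 14, 4)
  )
}

#' Scenario configuration for the five-assessment protocol simulator
#'
#' Bundles the study conditions the generator emulates: one baseline
#' angiography, three assessments under escalating norepinephrine infusion
#' (0.1, 0.5, 1.0 ug/kg/min) and a remnant assessment after
#' discontinuation; per-region logistic wash-in kinetics with dye
#' accumulation between injections; hemodynamics drawn from uniform ranges
#' bracketing the published per-time-point means +/- SD; capillary lactate
#' mostly censored "Low".
#'
#' @param dims frame dimensions (pixels), `c(H, W)`.
#' @param nROIs number of square regions of interest (the study uses 4).
#' @param roiSize side length of each square ROI in pixels (default a
#'   quarter of the frame's shorter side).
#' @param frameRate acquisition rate (Hz).
#' @param duration recording duration (s), must cover the 40-s analysis window.
#' @param retention fraction of each injection's amplitude retained as the
#'   next baseline (dye accumulation).
#' @param noiseSd additive detector noise SD (detector units).
#' @param detector detector transfer function, see [detectorResponse()].
#' @param detectorMax detector ceiling.
#' @param ampRange,tauRange,t0Range uniform sampling ranges for the
#'   per-region wash-in amplitude (detector units), rise time constant (s)
#'   and arrival time (s).
#' @param weightRange animal weight range (kg).
#' @param doseSchedule norepinephrine dose (ug/kg/min) at the five
#'   assessments; the fifth entry is the post-discontinuation remnant.
#' @param lactateLowProb probability that the lactate reading at each of
#'   the five assessments is censored ("Low", i.e. below 0.6 mmol/L).
#' @param lactateRange range of uncensored lactate draws (mmol/L).
#' @param quantize round recorded frames to integer detector units.
#' @param family wash-in curve family, see [washInTrace()].
#' @return a list of class `"fler_scenario"`.
#' @seealso [simulateProtocol()]
#' @export
protocolScenario <- function(dims = c(48, 48), nROIs = 4L, roiSize = NULL,
                             frameRate = 10, duration = 40, retention = 0.6,
                             noiseSd = 2, detector = "saturating",
                             detectorMax = 255,
                             ampRange = c(90, 130), tauRange = c(1.5, 2.5),
                             t0Range = c(9, 12), weightRange = c(33, 44),
                             doseSchedule = c(0, 0.1, 0.5, 1.0, 0),
                             lactateLowProb = c(0.4, 0.6, 0.6, 0.6, 0.8),
                             lactateRange = c(0.6, 1.3), quantize = TRUE,
                             family = "logistic") {
  if (length(doseSchedule) != 5L)
    stop("'doseSchedule' must give the dose at all 5 assessments", call. = FALSE)
  if (length(lactateLowProb) != 5L)
    stop("'lactateLowProb' must have length 5", call. = FALSE)
  if (is.null(roiSize)) roiSize <- max(2L, min(dims) %/% 4L)
  sc <- list(dims = as.integer(dims), nROIs = as.integer(nROIs),
             roiSize = as.integer(roiSize), frameRate = frameRate,
             duration = duration, retention = retention, noiseSd = noiseSd,
             detector = match.arg(detector, c("saturating", "linear")),
             detectorMax = detectorMax, ampRange = ampRange,
             tauRange = tauRange, t0Range = t0Range,
             weightRange = weightRange, doseSchedule = doseSchedule,
             lactateLowProb = lactateLowProb, lactateRange = lactateRange,
             quantize = isTRUE(quantize), family = family)
  class(sc) <- "fler_scenario"
  sc
}

#' Lay out square regions of interest on the frame grid
#'
#' Places `n` equally sized square ROIs on a regular grid with margins,
#' mirroring the operator-chosen bowel-surface regions of the study.
#'
#' @param dims frame dimensions `c(H, W)`.
#' @param n number of ROIs.
#' @param size ROI side length in pixels.
#' @return integer `H x W` label matrix; 0 is background, ROIs are 1..n.
#' @export
squareROILayout <- function(dims, n = 4L, size = NULL) {
  H <- dims[1L]; W <- dims[2L]
  if (is.null(size)) size <- max(2L, min(H, W) %/% 4L)
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  if (nrow_ * size > H || ncol_ * size > W)
    stop("ROIs do not fit inside the frame", call. = FALSE)
  labels <- matrix(0L, H, W)
  rc <- floor(seq(1, H - size + 1, length.out = nrow_ + 2))[2:(nrow_ + 1)]
  cc <- floor(seq(1, W - size + 1, length.out = ncol_ + 2))[2:(ncol_ + 1)]
  k <- 0L
  for (i in seq_len(nrow_)) for (j in seq_len(ncol_)) {
    if (k >= n) break
    k <- k + 1L
    labels[rc[i]:(rc[i] + size - 1L), cc[j]:(cc[j] + size - 1L)] <- k
  }
  labels
}

# Accepts either an integer label matrix or a list of logical masks;
# returns a label matrix, erroring on overlapping masks.
normalizeROILayout <- function(roiLayout) {
  if (is.matrix(roiLayout)) {
    storage.mode(roiLayout) <- "integer"
    return(roiLayout)
  }
  if (is.list(roiLayout)) {
    d <- dim(roiLayout[[1L]])
    cover <- matrix(0L, d[1L], d[2L])
    for (m in roiLayout) {
      if (!identical(dim(m), d)) stop("ROI masks must share dimensions", call. = FALSE)
      cover <- cover + (m != 0L)
    }
    if (any(cover > 1L))
      stop("regions overlap: ROI masks must cover disjoint pixel sets", call. = FALSE)
    labels <- matrix(0L, d[1L], d[2L])
    for (k in seq_along(roiLayout)) labels[roiLayout[[k]] != 0L] <- k
    return(labels)
  }
  stop("'roiLayout' must be a label matrix or a list of logical masks", call. = FALSE)
}

#' Simulate one fluorescence angiography sequence
#'
#' Generates an `H x W x T` stack in which every pixel of region `r`
#' follows the noiseless trace `B_r + A_r * S((t - t0_r)/tau_r)` (logistic
#' wash-in, see [washInTrace()]), passed through the detector transfer
#' function, with per-frame additive Gaussian noise of SD `sigma_r`, and
#' finally clipped to the detector range (and rounded to integer detector
#' units when `quantize = TRUE`). Fully deterministic given `seed`.
#'
#' @param paramsMap named list of [KineticParams-class], one per region
#'   label (`"1"`, `"2"`, ...). An optional `"0"` entry sets the background
#'   kinetics; otherwise the background is dark and noise-free.
#' @param roiLayout integer label matrix (0 = background) or list of
#'   disjoint logical masks; overlapping masks are an error.
#' @param duration recording length (s); must cover the 40-s analysis window.
#' @param frameRate frames per second.
#' @param seed RNG seed (required; the caller's RNG state is untouched).
#' @param injectionIndex which of the repeated injections this stack is.
#' @param detector,detectorMax detector model, see [detectorResponse()].
#' @param quantize round to integer detector units (8-bit videography
#'   convention; also guarantees a bit-exact TIFF round trip).
#' @param family wash-in curve family passed to [washInTrace()].
#' @param window analysis window the recording must cover (s).
#' @return a [FluorescenceSequence-class].
#' @examples
#' layout <- squareROILayout(c(16, 16), n = 1, size = 8)
#' seq1 <- simulateSequence(list("1" = kineticParams(10, 2, 100)), layout,
#'                          seed = 1, quantize = FALSE)
#' @export
simulateSequence <- function(paramsMap, roiLayout, duration = 40,
                             frameRate = 10, seed, injectionIndex = 1L,
                             detector = c("linear", "saturating"),
                             detectorMax = 255, quantize = TRUE,
                             family = "logistic", window = 40) {
  detector <- match.arg(detector)
  if (missing(seed)) stop("'seed' is required for reproducible simulation", call. = FALSE)
  if (duration < window)
    stop(sprintf("duration (%g s) must cover the %g-s analysis window",
                 duration, window), call. = FALSE)
  labels <- normalizeROILayout(roiLayout)
  H <- nrow(labels); W <- ncol(labels)
  present <- sort(unique(as.vector(labels)))
  for (lab in setdiff(present, 0L))
    if (is.null(paramsMap[[as.character(lab)]]))
      stop(sprintf("no kinetic parameters supplied for region %d", lab), call. = FALSE)

  t <- seq_len(round(duration * frameRate)) / frameRate
  Tn <- length(t)
  mat <- matrix(0, H * W, Tn)

  withSeed(seed, {
    for (lab in present) {
      p <- paramsMap[[as.character(lab)]]
      if (is.null(p)) p <- kineticParams(t0 = 0, tau = 1, A = 0, B = 0, sigma = 0)
      stopifnot(is(p, "KineticParams"))
      if (p@A > 0 && p@t0 + 5 * p@tau > window)
        warning(sprintf(
          "region %s: kinetics (t0 + 5 tau = %.1f s) do not settle within the %g-s window",
          as.character(lab), p@t0 + 5 * p@tau, window), call. = FALSE)
      idx <- which(as.vector(labels) == lab)
      ideal <- detectorResponse(washInTrace(t, p, family = family),
                                response = detector, ceiling = detectorMax)
      block <- matrix(ideal, nrow = length(idx), ncol = Tn, byrow = TRUE)
      if (p@sigma > 0)
        block <- block + matrix(rnorm(length(idx) * Tn, 0, p@sigma),
                                nrow = length(idx))
      mat[idx, ] <- block
    }
  })

  mat <- clamp(mat, 0, detectorMax)
  if (isTRUE(quantize)) mat <- round(mat)
  fluorescenceSequence(array(mat, c(H, W, Tn)), timestamps = t,
                       frameRate = frameRate,
                       injectionIndex = injectionIndex,
                       detectorMax = detectorMax)
}

#' Simulate the full five-assessment, five-animal study protocol
#'
#' For each animal: draws a weight and the ICG dose (0.1 mg/kg, rounded to
#' one decimal), per-region wash-in kinetics, hemodynamics at the eight
#' monitored time points (baseline, the start and the assessment of each of
#' three escalating norepinephrine doses, and the remnant assessment after
#' discontinuation), mostly-censored capillary lactate readings at the five
#' angiography time points, and one [FluorescenceSequence-class] per
#' injection with the baseline accumulating between injections
#' ([accumulateBaseline()]). Rise-time constants are held fixed within an
#' animal across assessments: the protocol emulates the study's finding
#' that vasopressor dose does not alter wash-in speed, while absolute
#' intensities drift with accumulation.
#'
#' @param nAnimals number of animals (>= 1).
#' @param seed RNG seed; all tabular output is bit-reproducible and stacks
#'   element-wise reproducible given the same seed and scenario.
#' @param scenario a [protocolScenario()] configuration.
#' @return A list of class `"fler_protocol"` with elements `records` (one
#'   data frame of per-time-point measurements for all animals, censored
#'   lactate encoded as the string `"Low"`), `sequences` (per animal, a
#'   list of five sequences), `kinetics` (ground-truth per-region kinetic
#'   parameters per injection), `roiLayout` (label matrix), `scenario`, and
#'   `seed`.
#' @export
simulateProtocol <- function(nAnimals = 5L, seed, scenario = protocolScenario()) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!inherits(scenario, "fler_scenario")) stop("'scenario' must come from protocolScenario()", call. = FALSE)
  nAnimals <- as.integer(nAnimals)
  if (is.na(nAnimals) || nAnimals < 1L)
    stop("'nAnimals' must be at least 1", call. = FALSE)

  hm <- .hemodynamicMoments()
  labels <- squareROILayout(scenario$dims, n = scenario$nROIs,
                            size = scenario$roiSize)

  recs <- list(); kin <- list(); subseeds <- NULL
  withSeed(seed, {
    subseeds <- matrix(sample.int(2^30, nAnimals * 5L), nrow = nAnimals)
    for (a in seq_len(nAnimals)) {
      weight <- round(runif(1, scenario$weightRange[1L], scenario$weightRange[2L]), 1)
      icg <- round(weight / 10, 1)
      sys <- round(runif(nrow(hm), hm$sys_mean - hm$sys_sd, hm$sys_mean + hm$sys_sd))
      dia <- round(runif(nrow(hm), hm$dia_mean - hm$dia_sd, hm$dia_mean + hm$dia_sd))
      dia <- pmin(dia, sys - 5)
      hr <- round(runif(nrow(hm), hm$hr_mean - hm$hr_sd, hm$hr_mean + hm$hr_sd))
      lact <- rep(NA_character_, nrow(hm))
      icga <- which(!is.na(hm$assessment))
      for (k in seq_along(icga)) {
        lact[icga[k]] <- if (runif(1) < scenario$lactateLowProb[k]) "Low" else
          sprintf("%.1f", round(runif(1, scenario$lactateRange[1L],
                                      scenario$lactateRange[2L]), 1))
      }
      ne <- hm$ne_dose
      ne[icga] <- scenario$doseSchedule
      recs[[a]] <- data.frame(
        animal_id = sprintf("pig%02d", a), weight_kg = weight,
        icg_dose_mg = icg, timepoint_min = hm$timepoint_min,
        assessment = hm$assessment, ne_dose = ne, systolic = sys,
        diastolic = dia, hr = hr, lactate = lact,
        stringsAsFactors = FALSE)

      base <- lapply(seq_len(scenario$nROIs), function(r)
        kineticParams(
          t0 = runif(1, scenario$t0Range[1L], scenario$t0Range[2L]),
          tau = runif(1, scenario$tauRange[1L], scenario$tauRange[2L]),
          A = runif(1, scenario$ampRange[1L], scenario$ampRange[2L]),
          B = 0, sigma = scenario$noiseSd))
      p <- base
      for (k in 1:5) {
        for (r in seq_len(scenario$nROIs))
          kin[[length(kin) + 1L]] <- data.frame(
            animal_id = sprintf("pig%02d", a), injection = k, roi = r,
            t0 = p[[r]]@t0, tau = p[[r]]@tau, A = p[[r]]@A, B = p[[r]]@B,
            sigma = p[[r]]@sigma)
        if (k < 5) p <- lapply(p, accumulateBaseline, retention = scenario$retention)
      }
    }
  })

  kinetics <- do.call(rbind, kin)
  sequences <- vector("list", nAnimals)
  for (a in seq_len(nAnimals)) {
    sequences[[a]] <- vector("list", 5L)
    for (k in 1:5) {
      rows <- kinetics[kinetics$animal_id == sprintf("pig%02d", a) &
                         kinetics$injection == k, ]
      pm <- lapply(seq_len(nrow(rows)), function(i)
        kineticParams(rows$t0[i], rows$tau[i], rows$A[i], rows$B[i], rows$sigma[i]))
      names(pm) <- as.character(rows$roi)
      sequences[[a]][[k]] <- simulateSequence(
        pm, labels, duration = scenario$duration,
        frameRate = scenario$frameRate, seed = subseeds[a, k],
        injectionIndex = k, detector = scenario$detector,
        detectorMax = scenario$detectorMax, quantize = scenario$quantize,
        family = scenario$family)
    }
  }

  out <- list(records = do.call(rbind, recs), sequences = sequences,
              kinetics = kinetics, roiLayout = labels, scenario = scenario,
              seed = seed)
  class(out) <- "fler_protocol"
  out
}

#' @export
print.fler_protocol <- function(x, ...) {
  n <- length(x$sequences)
  cat(sprintf("fler protocol: %d animal(s) x 5 injections, %dx%d frames, %d ROIs\n",
              n, x$scenario$dims[1L], x$scenario$dims[2L], x$scenario$nROIs))
  invisible(x)
}
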