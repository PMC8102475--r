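# reproduction of the study's summary tables

#' Reproduce the study-level summary tables from per-animal data
#'
#' From a records table (and optionally per-animal, per-assessment rise
#' time and intensity summaries from the imaging pipeline) computes:
#' \describe{
#'   \item{`animals`}{weight mean and SD (n-1 convention), per-pig ICG
#'     doses.}
#'   \item{`hemodynamics`}{per-time-point means and SDs of heart rate and
#'     blood pressure across animals (integer rounding at emission) and,
#'     at assessment time points, the censored lactate mean and the
#'     observed range string (`"Low---max"`).}
#'   \item{`ttp`}{per-assessment mean and SD of the animals' mean rise
#'     times, the mean difference of each post-baseline assessment versus
#'     baseline (sign convention: assessment minus baseline) and the
#'     paired two-sided p-value. Requires `ttpSummaries`.}
#'   \item{`intensity`}{per-assessment means of `fi_min`, `fi_max`,
#'     `fi_diff` with successive percent changes (the change from a zero
#'     baseline minimum is undefined and reported `NA`). Requires
#'     `fiSummaries`.}
#' }
#' No multiple-testing correction is applied to the four contrasts,
#' mirroring the study's analysis. Rounding happens only at emission;
#' intermediate math is unrounded.
#'
#' @param records records data frame (see [loadTable1Records()]).
#' @param ttpSummaries optional data frame with columns `animal_id`,
#'   `assessment`, `mean_ttp` (one row per animal and assessment).
#' @param fiSummaries optional data frame with columns `animal_id`,
#'   `assessment`, `fi_min`, `fi_max`, `fi_diff`.
#' @param lactateSubstitute constant for censored lactate readings
#'   (mmol/L), see [censoredMean()].
#' @return list of data frames `animals`, `hemodynamics`, `ttp` (or
#'   `NULL`), `intensity` (or `NULL`).
#' @examples
#' rep1 <- reproduceTables(loadTable1Records())
#' rep1$animals$weight_mean                       # 40.3
#' subset(rep1$hemodynamics, assessment == 4)$hr  # 129
#' @export
reproduceTables <- function(records, ttpSummaries = NULL, fiSummaries = NULL,
                            lactateSubstitute = 0.6) {
  validateAnimalRecords(records)

  w <- unique(records[, c("animal_id", "weight_kg", "icg_dose_mg")])
  animals <- list(
    n = nrow(w),
    weight_mean = round(mean(w$weight_kg), 1),
    weight_sd = round(sd(w$weight_kg), 2),
    doses = data.frame(animal_id = w$animal_id, icg_dose_mg = w$icg_dose_mg))

  tps <- sort(unique(records$timepoint_min))
  hemo <- do.call(rbind, lapply(tps, function(tp) {
    r <- records[records$timepoint_min == tp, ]
    asm <- unique(r$assessment)
    lact <- r$lactate[!is.na(r$lactate)]
    lmean <- if (length(lact)) censoredMean(lact, substitute = lactateSubstitute) else NA_real_
    lrange <- if (length(lact)) {
      p <- parseLactate(lact)
      hi <- suppressWarnings(max(p$value, na.rm = TRUE))
      if (any(p$censored)) {
        if (is.finite(hi)) sprintf("Low-%.2f", hi) else "Low"
      } else sprintf("%.2f-%.2f", min(p$value), hi)
    } else NA_character_
    data.frame(timepoint_min = tp, assessment = asm[1L],
               ne_dose = r$ne_dose[1L],
               hr = round(mean(r$hr)), hr_sd = round(sd(r$hr)),
               systolic = round(mean(r$systolic)), systolic_sd = round(sd(r$systolic)),
               diastolic = round(mean(r$diastolic)), diastolic_sd = round(sd(r$diastolic)),
               lactate_mean = lmean, lactate_range = lrange,
               stringsAsFactors = FALSE)
  }))

  ttpTab <- NULL
  if (!is.null(ttpSummaries)) {
    ttpTab <- .contrastTable(ttpSummaries, "mean_ttp", digits = 2)
  }

  fiTab <- NULL
  if (!is.null(fiSummaries)) {
    agg <- function(col) sapply(1:5, function(k)
      mean(fiSummaries[[col]][fiSummaries$assessment == k]))
    fmin <- agg("fi_min"); fmax <- agg("fi_max"); fdiff <- agg("fi_diff")
    fiTab <- data.frame(
      assessment = 1:5,
      fi_min = round(fmin, 1), fi_max = round(fmax, 1),
      fi_diff = round(fdiff, 1),
      pct_min = trajectoryPercentChanges(fmin),
      pct_max = trajectoryPercentChanges(fmax))
  }

  list(animals = animals, hemodynamics = hemo, ttp = ttpTab, intensity = fiTab)
}

# per-assessment mean +- SD of a per-animal metric, with paired contrasts
# of assessments 2..5 against baseline (assessment - baseline sign)
.contrastTable <- function(summaries, col, digits = 2) {
  need <- c("animal_id", "assessment", col)
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- sort(unique(summaries$animal_id))
  m <- sapply(1:5, function(k) {
    r <- summaries[summaries$assessment == k, ]
    if (!all(ids %in% r$animal_id))
      stop(sprintf("missing assessment %d for some animals", k), call. = FALSE)
    r[[col]][match(ids, r$animal_id)]
  })                                    # animals x 5
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  out <- data.frame(
    assessment = 1:5,
    mean = round(colMeans(m), digits),
    sd = round(apply(m, 2L, sd), digits),
    mean_diff = NA_real_, p = NA_real_)
  for (k in 2:5) {
    ct <- pairedTTest(m[, k], m[, 1L],
                      label = sprintf("assessment %d vs baseline", k))
    out$mean_diff[k] <- round(ct$mean_diff, digits)
    out$p[k] <- ct$p
  }
  out
}
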