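# embedded study data: per-pig measurements and published summary values

#' Load the per-pig measurement table of the porcine study
#'
#' Returns the published per-animal records of the five-pig protocol:
#' weight, ICG dose (0.1 mg/kg), and systolic/diastolic blood pressure,
#' heart rate and local capillary lactate at the eight monitored time
#' points (five angiography assessments plus the start of each
#' norepinephrine dose). Censored lactate readings (between 0.1 and
#' 0.59 mmol/L, below the analyser's reporting range) are encoded as the
#' literal string `"Low"`; lactate is `NA` at non-assessment time points.
#'
#' @return data frame with columns `animal_id`, `weight_kg`, `icg_dose_mg`,
#'   `timepoint_min`, `assessment` (1--5 at angiography time points, `NA`
#'   otherwise), `ne_dose` (ug/kg/min), `systolic`, `diastolic`, `hr`,
#'   `lactate` (character).
#' @examples
#' recs <- loadTable1Records()
#' unique(recs$weight_kg)        # 33.0 42.1 41.4 41.0 44.0
#' @export
loadTable1Records <- function() {
  path <- system.file("extdata", "table1_pigs.csv", package = "flerq",
                      mustWork = TRUE)
  readRecordsCSV(path)
}

#' Validate a per-animal records table
#'
#' Checks the structural invariants of the study records: exactly five
#' assessments per animal, ICG dose equal to one tenth of the weight
#' rounded to one decimal, positive heart rate, systolic above diastolic
#' pressure, and lactate encoded as a number or `"Low"`.
#'
#' @param records a records data frame (see [loadTable1Records()]).
#' @return `records`, invisibly; errors describe the first violation.
#' @export
validateAnimalRecords <- function(records) {
  need <- c("animal_id", "weight_kg", "icg_dose_mg", "assessment",
            "ne_dose", "systolic", "diastolic", "hr", "lactate")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (id in unique(records$animal_id)) {
    r <- records[records$animal_id == id, ]
    a <- sort(r$assessment[!is.na(r$assessment)])
    if (!identical(as.integer(a), 1:5))
      stop(sprintf("animal %s must have exactly assessments 1..5", id), call. = FALSE)
    w <- unique(r$weight_kg)
    if (length(w) != 1L || !isTRUE(all.equal(unique(r$icg_dose_mg), round(w / 10, 1))))
      stop(sprintf("animal %s: ICG dose must be round(weight/10, 1) mg", id), call. = FALSE)
  }
  if (any(records$hr <= 0)) stop("heart rate must be positive", call. = FALSE)
  if (any(records$systolic <= records$diastolic) || any(records$diastolic <= 0))
    stop("blood pressure must satisfy systolic > diastolic > 0", call. = FALSE)
  lac <- records$lactate[!is.na(records$lactate)]
  num <- suppressWarnings(as.numeric(lac))
  bad <- is.na(num) & tolower(lac) != "low"
  if (any(bad))
    stop("lactate entries must be numeric or the literal 'Low'", call. = FALSE)
  if (any(num < 0.6, na.rm = TRUE))
    stop("uncensored lactate values must be >= 0.6 mmol/L", call. = FALSE)
  invisible(records)
}

#' Published per-assessment summary values
#'
#' The study's printed group-level summaries, used as inputs for the
#' worked-example arithmetic (baseline contrasts, percent intensity
#' changes) that the per-pixel pipeline reproduces qualitatively on
#' synthetic data. `ttp` holds the mean +/- SD rise time (s) of the four
#' ROIs across the five assessments with the reported paired p-values
#' versus baseline; `intensity` holds the mean minimum and maximum
#' absolute fluorescence intensities of the four ROIs.
#'
#' @return a list with data frames `ttp` and `intensity`.
#' @examples
#' pub <- publishedSummaries()
#' round(pub$ttp$mean - pub$ttp$mean[1], 2)[-1]   # -0.18 -0.51  0.19  1.58
#' @export
publishedSummaries <- function() {
  list(
    ttp = data.frame(
      assessment = 1:5,
      mean = c(4.41, 4.23, 3.90, 4.60, 5.99),
      sd = c(0.46, 0.30, 0.16, 0.68, 2.07),
      p_vs_baseline = c(NA, 0.204, 0.119, 0.555, 0.110)),
    intensity = data.frame(
      assessment = 1:5,
      fi_min = c(0, 62.7, 98.3, 127.1, 134.2),
      fi_max = c(101.4, 146.6, 150.4, 162.1, 159.0))
  )
}
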