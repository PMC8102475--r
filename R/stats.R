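# study-level statistics

#' Parse lactate readings with censoring flags
#'
#' The point-of-care analyser reports readings between 0.1 and 0.59 mmol/L
#' only as `"Low"`. This helper splits a vector of readings (numeric, or
#' character with the literal `"Low"`) into values and censoring flags.
#'
#' @param x numeric or character vector; `NA` entries are dropped by the
#'   summary functions.
#' @return list with `value` (numeric, `NA` where censored) and `censored`
#'   (logical).
#' @export
parseLactate <- function(x) {
  if (is.numeric(x)) return(list(value = x, censored = rep(FALSE, length(x))))
  cens <- !is.na(x) & tolower(trimws(x)) == "low"
  val <- suppressWarnings(as.numeric(x))
  if (any(!cens & !is.na(x) & is.na(val)))
    stop("lactate entries must be numeric or 'Low'", call. = FALSE)
  list(value = val, censored = cens)
}

#' Mean lactate with censored values substituted
#'
#' Censored (`"Low"`) readings lie in 0.1--0.59 mmol/L; substituting a
#' fixed constant at the top of that interval before averaging prevents
#' underestimation bias. The default substitute is 0.6 mmol/L, the
#' analyser's reporting limit: this is the constant that reproduces the
#' published per-assessment means exactly (the value 0.59 quoted as the
#' substitution rule in the study text does not; see the methods
#' vignette), and it is exposed as a parameter.
#'
#' @param x lactate readings (see [parseLactate()]); `NA`s are dropped.
#' @param substitute constant imputed for censored readings (mmol/L).
#' @param digits rounding applied to the reported mean (default 2);
#'   `NULL` for no rounding.
#' @return mean lactate in mmol/L.
#' @examples
#' censoredMean(c("0.8", "Low", "0.6", "1.1", "Low"))   # 0.74
#' @export
censoredMean <- function(x, substitute = 0.6, digits = 2) {
  p <- parseLactate(x)
  keep <- p$censored | !is.na(p$value)
  if (!any(keep)) stop("no lactate readings to average", call. = FALSE)
  v <- ifelse(p$censored[keep], substitute, p$value[keep])
  m <- mean(v)
  if (!is.null(digits)) m <- round(m, digits)
  m
}

#' Paired two-sided t-test for per-animal contrasts
#'
#' Computes `d = x - y` per animal and tests whether its mean differs from
#' zero: `t = mean(d) / (sd(d)/sqrt(n))` with the sample (n-1) standard
#' deviation and a two-sided p-value from the Student t distribution with
#' `n - 1` degrees of freedom. Each animal serves as its own control, as
#' in the study design. If all differences are identical the statistic is
#' degenerate: `p = 0` for a nonzero mean difference, undefined (`NA`)
#' otherwise; the `degenerate` flag is set either way.
#'
#' @param x,y paired per-animal values (equal length `n >= 2`, no missing
#'   pairs).
#' @param label contrast label carried into the output.
#' @return one-row data frame: `contrast`, `n`, `mean_diff`, `sd_diff`,
#'   `t`, `df`, `p`, `degenerate`.
#' @examples
#' # differences 1..5: t = 3 / (sd(1:5)/sqrt(5)) = 4.243 on 4 df
#' pairedTTest(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
#' @export
pairedTTest <- function(x, y, label = "x vs y") {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing pairs are not allowed", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  md <- mean(d)
  sdd <- sd(d)
  degenerate <- sdd == 0
  if (degenerate) {
    tstat <- if (md == 0) NA_real_ else sign(md) * Inf
    p <- if (md == 0) NA_real_ else 0
  } else {
    tstat <- md / (sdd / sqrt(n))
    p <- 2 * pt(-abs(tstat), df = n - 1L)
  }
  data.frame(contrast = label, n = n, mean_diff = md, sd_diff = sdd,
             t = tstat, df = n - 1L, p = p, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Percent change between consecutive assessments
#'
#' `round(100 * (curr - prev) / prev)` to the nearest integer, matching
#' the study's reporting convention. A non-positive `prev` (e.g. the zero
#' minimum intensity at a dye-free baseline) leaves the change undefined
#' and is an error; trajectory helpers report it as `NA`.
#'
#' @param prev,curr values at the previous and current assessment.
#' @return integer percent change.
#' @examples
#' percentChange(62.7, 98.3)   # 57
#' @export
percentChange <- function(prev, curr) {
  if (!is.finite(prev) || prev <= 0)
    stop("percent change from a non-positive previous value is undefined",
         call. = FALSE)
  as.integer(round(100 * (curr - prev) / prev))
}

#' Successive percent changes along an assessment trajectory
#'
#' @param values per-assessment values, in protocol order.
#' @return integer vector of length `length(values)`; the first entry and
#'   any step starting from a non-positive value are `NA`.
#' @export
trajectoryPercentChanges <- function(values) {
  n <- length(values)
  out <- rep(NA_integer_, n)
  for (k in seq_len(n - 1L)) {
    if (is.finite(values[k]) && values[k] > 0)
      out[k + 1L] <- percentChange(values[k], values[k + 1L])
  }
  out
}
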