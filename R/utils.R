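# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so simulation calls do not
#' perturb the global random stream.
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Centered moving average with truncated edge windows
#'
#' Window `k` must be odd; edges use the available frames only, so the
#' output has the same length as the input and a flat trace stays flat.
#' @noRd
movingAverage <- function(x, k = 3L) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# row-wise moving average of a T x N matrix (over time, per column)
movingAverageMat <- function(X, k = 3L) {
  k <- as.integer(k)
  if (k <= 1L) return(X)
  if (k %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  n <- nrow(X)
  h <- (k - 1L) %/% 2L
  cs <- rbind(0, apply(X, 2L, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# first index at which each column of logical matrix M is TRUE; NA if never
firstTrueIndex <- function(M) {
  n <- nrow(M)
  cm <- apply(M, 2L, cummax)
  if (!is.matrix(cm)) cm <- matrix(cm, nrow = n)
  counts <- colSums(cm)
  idx <- n + 1L - counts
  idx[counts == 0L] <- NA_integer_
  as.integer(idx)
}
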