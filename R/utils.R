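#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed
#'
#' Deterministic arithmetic substream derivation so that per-subject,
#' per-iteration and per-resample random streams can be reconstructed from a
#' single master seed without consuming the global RNG state.
#'
#' @param seed master seed (integer).
#' @param k substream index (integer >= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by Lehmer generators
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + (as.numeric(k) + 1) * 7919) %% m
  s <- (s * 48271) %% m
  as.integer(if (s < 1) 1 else s)
}

# Evaluate an expression with a local RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Runs of TRUE in a logical vector -> data.frame(start, end, length) (indices).
logical_runs <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Remove TRUE-runs shorter than min_run from a logical vector.
filter_short_runs <- function(x, min_run) {
  runs <- logical_runs(x)
  out <- rep(FALSE, length(x))
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  if (nrow(runs) > 0) {
    for (i in seq_len(nrow(runs))) out[runs$start[i]:runs$end[i]] <- TRUE
  }
  out
}

#' Centered moving-average smoothing of a decoding time course
#'
#' Five points at a 50 Hz feature rate correspond to a +/-40 ms window. At the
#' series edges the window is truncated (shrinking window); no data are
#' invented beyond the series.
#'
#' @param x numeric vector (e.g., accuracy per time point).
#' @param smoothing_points odd window length in points (default 5).
#' @return numeric vector of the same length.
#' @export
smooth_timecourse <- function(x, smoothing_points = 5) {
  stopifnot(is.numeric(x))
  k <- as.integer(smoothing_points)
  if (k %% 2L != 1L || k < 1L) stop("smoothing_points must be a positive odd integer")
  if (k > length(x)) stop("smoothing window longer than the series")
  half <- (k - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Pearson correlation of one vector against the columns of a matrix, plus the
# two-tailed p from the t transform (identical to cor.test's parametric p).
pearson_cols <- function(y, X) {
  n <- length(y)
  stopifnot(nrow(X) == n, n >= 4)
  r <- suppressWarnings(as.vector(stats::cor(y, X)))
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p)
}
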