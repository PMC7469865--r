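#' One-tailed signed-rank test of decoding accuracy against chance
#'
#' Wilcoxon signed-rank test of median accuracy > 0.5 at each time point.
#' Zero differences are dropped (standard convention); the exact null
#' distribution is used for n <= 25 informative subjects (when no ties are
#' present), the normal approximation with continuity correction otherwise.
#' A time point where every subject sits exactly at chance yields p = 1 with
#' a warning.
#'
#' @param accuracy subjects x time matrix of decoding accuracies.
#' @param chance chance level (default 0.5).
#' @return numeric vector of one-tailed p values per time point.
#' @export
signed_rank_timecourse <- function(accuracy, chance = 0.5) {
  accuracy <- as.matrix(accuracy)
  n <- nrow(accuracy)
  if (n < 6) stop("signed-rank timecourse requires >= 6 subjects")
  degenerate <- 0L
  p <- apply(accuracy, 2, function(a) {
    d <- a - chance
    if (all(d == 0)) {
      degenerate <<- degenerate + 1L
      return(1)
    }
    suppressWarnings(
      stats::wilcox.test(d, alternative = "greater",
                         exact = sum(d != 0) <= 25, correct = TRUE)$p.value)
  })
  if (degenerate > 0)
    warning(degenerate, " time point(s) with all accuracies exactly at chance; p = 1 there")
  p
}

#' FDR correction with a contiguity filter
#'
#' Benjamini-Hochberg step-up across time points at level `q`, followed by
#' removal of significant runs shorter than `min_run` contiguous points
#' (controls isolated time points that pass correction by chance).
#'
#' @param p per-timepoint p values.
#' @param q FDR level (default 0.05).
#' @param min_run minimum run length kept (default 3).
#' @param method `"BH"` (default) or `"BY"`.
#' @return list of class `significance_mask`: `p`, `q` (adjusted),
#'   `mask` (logical after contiguity filtering), `clusters`
#'   (data.frame of surviving runs), plus the parameters.
#' @export
fdr_contiguity_mask <- function(p, q = 0.05, min_run = 3, method = c("BH", "BY")) {
  method <- match.arg(method)
  padj <- stats::p.adjust(p, method = method)
  sig <- padj < q
  mask <- filter_short_runs(sig, min_run)
  structure(list(p = p, q_adjusted = padj, mask = mask,
                 clusters = logical_runs(mask), q = q, min_run = min_run,
                 method = method),
            class = "significance_mask")
}

#' Extract the decoding onset from a significance mask
#'
#' The onset is the time of the earliest significant point at or after 0 ms
#' (post-event); significant points before the locking event, which can
#' occur under noise, are never reported as onsets.
#'
#' @param mask a `significance_mask` from [fdr_contiguity_mask()].
#' @param time time axis in ms, same length as the mask.
#' @return onset in ms, or `NA` if no significant point lies at/after 0 ms.
#' @export
extract_onset <- function(mask, time) {
  m <- mask$mask & (time >= 0)
  if (!any(m)) return(NA_real_)
  time[which(m)[1]]
}

#' Bootstrap distribution of decoding onsets
#'
#' Resamples subjects with replacement; each resample reruns the whole
#' chain (signed-rank tests, FDR correction, contiguity filter, onset
#' extraction). Resamples without a detectable onset are recorded as
#' missing and excluded from the summary (their count is reported).
#'
#' @param accuracy subjects x time matrix (smoothed accuracies).
#' @param time time axis, ms.
#' @param n_boot number of resamples (default 100).
#' @param q,min_run passed to [fdr_contiguity_mask()].
#' @param seed RNG seed.
#' @return list of class `onset_distribution`: `onsets` (ms, with NAs),
#'   `mean`, `sd`, `n_missing`.
#' @export
bootstrap_onsets <- function(accuracy, time, n_boot = 100, q = 0.05,
                             min_run = 3, seed = 1) {
  accuracy <- as.matrix(accuracy)
  n <- nrow(accuracy)
  if (n < 2) stop("need >= 2 subjects")
  onsets <- vapply(seq_len(n_boot), function(b) {
    idx <- with_seed(derive_seed(seed, b), sample.int(n, n, replace = TRUE))
    p <- signed_rank_timecourse(accuracy[idx, , drop = FALSE])
    extract_onset(fdr_contiguity_mask(p, q = q, min_run = min_run), time)
  }, numeric(1))
  if (all(is.na(onsets))) stop("no bootstrap resample yielded an onset")
  structure(list(onsets = onsets, mean = mean(onsets, na.rm = TRUE),
                 sd = stats::sd(onsets, na.rm = TRUE),
                 n_missing = sum(is.na(onsets)), n_boot = n_boot),
            class = "onset_distribution")
}

#' @export
print.onset_distribution <- function(x, ...) {
  cat(sprintf("<onset_distribution> %.1f +/- %.1f ms (%d/%d resamples with onset)\n",
              x$mean, x$sd, x$n_boot - x$n_missing, x$n_boot))
  invisible(x)
}

#' Compare two bootstrap onset distributions
#'
#' Pooled-variance two-sample t test on the bootstrap onset values (the
#' conventional comparison for two 100-resample onset distributions,
#' giving 198 degrees of freedom).
#'
#' @param dist_a,dist_b `onset_distribution` objects.
#' @return `htest` from [stats::t.test()].
#' @export
compare_onsets <- function(dist_a, dist_b) {
  a <- dist_a$onsets[!is.na(dist_a$onsets)]
  b <- dist_b$onsets[!is.na(dist_b$onsets)]
  if (length(a) < 2 || length(b) < 2) stop("distributions too small")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) stop("zero variance in both distributions")
  stats::t.test(a, b, var.equal = TRUE)
}

#' Window-averaged decoding accuracy per subject
#'
#' Mean accuracy over each analysis window (half-open `[start, end)` so that
#' adjacent early/late windows do not share their boundary point).
#'
#' @param accuracy subjects x time matrix.
#' @param time time axis, ms.
#' @param windows named list of ms pairs, e.g.
#'   `list(early = c(200, 700), late = c(700, 1200))`.
#' @return subjects x windows matrix.
#' @export
window_average_accuracy <- function(accuracy, time, windows) {
  accuracy <- as.matrix(accuracy)
  out <- sapply(windows, function(w) {
    sel <- time >= w[1] & time < w[2]
    if (!any(sel)) stop("empty accuracy window")
    rowMeans(accuracy[, sel, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(accuracy))
  colnames(out) <- names(windows)
  out
}
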