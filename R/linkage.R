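#' Between-subject correlation time course
#'
#' Pearson correlation (two-tailed) between a per-subject scalar (behavior
#' or N1 attention modulation) and decoding accuracy at each time point.
#'
#' @param accuracy subjects x time matrix.
#' @param behavior per-subject scalar vector.
#' @param time time axis, ms (optional; carried through).
#' @return list of class `correlation_timecourse`: `r`, `p` (two-tailed),
#'   `time`, `n`.
#' @export
corr_timecourse <- function(accuracy, behavior, time = NULL) {
  accuracy <- as.matrix(accuracy)
  n <- length(behavior)
  if (nrow(accuracy) != n) stop("subject counts do not match")
  if (n < 4) stop("need >= 4 subjects")
  if (anyNA(accuracy) || anyNA(behavior)) stop("missing values not allowed")
  res <- pearson_cols(behavior, accuracy)
  if (any(!is.finite(res$r)))
    warning("zero variance at some time points; r undefined there")
  structure(list(r = res$r, p = res$p, time = time, n = n),
            class = "correlation_timecourse")
}

#' Liptak-Stouffer combination of per-dataset p values
#'
#' Each dataset's p value is converted to a Z score,
#' `Z_i = qnorm(1 - p_i)`, and combined with square-root-of-N weights:
#' `Z = sum(w_i Z_i) / sqrt(sum(w_i^2))` with `w_i = sqrt(N_i)`; the
#' combined p is `1 - pnorm(Z)`. With a single dataset the combination is
#' the identity. p values are clipped to `[1e-12, 1 - 1e-12]` before the
#' probit transform (finite machine behavior on extreme inputs).
#'
#' @param p_list list of per-dataset p vectors (aligned time axes).
#' @param ns integer vector of subjects per dataset.
#' @return list of class `meta_combine`: `z_per_dataset`, `z`, `p`,
#'   `weights`.
#' @export
liptak_stouffer <- function(p_list, ns) {
  if (!is.list(p_list)) p_list <- list(p_list)
  if (length(p_list) != length(ns)) stop("one N per dataset required")
  len <- unique(vapply(p_list, length, integer(1)))
  if (length(len) != 1) stop("p vectors must share a time axis")
  eps <- 1e-12
  clipped <- lapply(p_list, function(p) {
    if (any(p <= 0 | p >= 1)) warning("p values clipped to (0, 1)")
    pmin(pmax(p, eps), 1 - eps)
  })
  z_i <- lapply(clipped, function(p) stats::qnorm(1 - p))
  w <- sqrt(ns)
  zmat <- do.call(rbind, z_i)
  z <- as.vector(crossprod(w, zmat)) / sqrt(sum(w^2))
  structure(list(z_per_dataset = z_i, z = z, p = 1 - stats::pnorm(z),
                 weights = w, ns = ns),
            class = "meta_combine")
}

# Correlation p values for a set of subject shuffles, sharing each shuffle
# across all time points. Z-standardize once; r = Z_b' Z_acc / (n-1).
perm_corr_p <- function(accuracy, behavior, perms) {
  n <- length(behavior)
  Za <- scale(accuracy)                   # n x T
  Za[, attr(Za, "scaled:scale") == 0] <- 0
  zb <- as.vector(scale(behavior))
  B <- matrix(zb[perms], nrow = n)        # n x n_perm (perms: n x n_perm index matrix)
  r <- crossprod(B, Za) / (n - 1)         # n_perm x T
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df)
}

largest_run <- function(sig) {
  r <- logical_runs(sig)
  if (nrow(r) == 0) 0L else max(r$length)
}

#' Cluster-size permutation test with shared subject shuffles
#'
#' Observed clusters are maximal runs of time points whose (combined, for
#' multiple datasets) correlation p value is below `alpha`; minimal cluster
#' size is 1. The null distribution of the largest cluster size is built by
#' shuffling the subject pairing between behavior and accuracy within each
#' dataset -- the same shuffle applied at every time point of an iteration,
#' preserving the temporal autocorrelation of the accuracy time courses --
#' then recomputing per-point p values (combining across datasets when more
#' than one is supplied) and recording the largest significant run (0 when
#' none). Each observed cluster's p value is the fraction of null values
#' greater than or equal to its size (ties count as exceeding); when the
#' observed size exceeds every null value the p value is reported as
#' `< 1/n_perm` via the `p_less_than` flag.
#'
#' @param accuracy_list list of subjects x time matrices (one per dataset;
#'   time axes must match exactly -- no interpolation is performed).
#' @param behavior_list list of per-subject scalar vectors.
#' @param time time axis, ms.
#' @param n_perm permutation iterations (default 1000; fewer than 100
#'   triggers a warning about tail instability).
#' @param alpha per-point cluster-forming threshold (default 0.05).
#' @param seed RNG seed; shuffles are uniform permutations (identity
#'   allowed, standard exchangeability argument).
#' @return list of class `permutation_result`: `clusters` (data.frame with
#'   start/end ms, size, p, p_less_than), `null_sizes`, `observed_p`
#'   (per-point), `r_per_dataset`, `alpha`.
#' @export
cluster_permutation <- function(accuracy_list, behavior_list, time,
                                n_perm = 1000, alpha = 0.05, seed = 1) {
  if (is.matrix(accuracy_list)) accuracy_list <- list(accuracy_list)
  if (is.numeric(behavior_list)) behavior_list <- list(behavior_list)
  nd <- length(accuracy_list)
  if (length(behavior_list) != nd) stop("one behavior vector per dataset")
  nt <- unique(vapply(accuracy_list, ncol, integer(1)))
  if (length(nt) != 1) stop("datasets must share an identical time axis")
  if (length(time) != nt) stop("time axis length mismatch")
  if (n_perm < 100) warning("fewer than 100 permutations: unstable tail")
  ns <- vapply(behavior_list, length, integer(1))

  obs <- lapply(seq_len(nd), function(i)
    pearson_cols(behavior_list[[i]], accuracy_list[[i]]))
  obs_p_per <- lapply(obs, `[[`, "p")
  obs_p <- if (nd > 1) liptak_stouffer(obs_p_per, ns)$p else obs_p_per[[1]]
  clusters <- logical_runs(obs_p < alpha)

  # null distribution: one shared subject shuffle per dataset per iteration
  perm_p <- vector("list", nd)
  for (i in seq_len(nd)) {
    perms <- with_seed(derive_seed(seed, i), {
      vapply(seq_len(n_perm), function(b) sample.int(ns[i]), integer(ns[i]))
    })
    perm_p[[i]] <- perm_corr_p(accuracy_list[[i]], behavior_list[[i]], perms)
  }
  null_p <- if (nd > 1) {
    eps <- 1e-12
    zs <- lapply(perm_p, function(P) stats::qnorm(1 - pmin(pmax(P, eps), 1 - eps)))
    w <- sqrt(ns)
    Z <- Reduce(`+`, Map(function(z, wi) wi * z, zs, w)) / sqrt(sum(w^2))
    1 - stats::pnorm(Z)
  } else perm_p[[1]]
  null_sizes <- apply(null_p < alpha, 1, largest_run)

  if (nrow(clusters) > 0) {
    clusters$start_ms <- time[clusters$start]
    clusters$end_ms <- time[clusters$end]
    clusters$size <- clusters$length
    clusters$p <- vapply(clusters$size, function(sz) mean(null_sizes >= sz),
                         numeric(1))
    clusters$p_less_than <- vapply(clusters$size,
                                   function(sz) all(null_sizes < sz), logical(1))
    clusters$mean_r <- vapply(seq_len(nrow(clusters)), function(k) {
      idx <- clusters$start[k]:clusters$end[k]
      mean(vapply(obs, function(o) mean(o$r[idx]), numeric(1)))
    }, numeric(1))
  } else {
    clusters <- data.frame(start = integer(0), end = integer(0),
                           length = integer(0), start_ms = numeric(0),
                           end_ms = numeric(0), size = integer(0),
                           p = numeric(0), p_less_than = logical(0),
                           mean_r = numeric(0))
  }
  structure(list(clusters = clusters, null_sizes = null_sizes,
                 observed_p = obs_p,
                 r_per_dataset = lapply(obs, `[[`, "r"),
                 time = time, alpha = alpha, n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d cluster(s), %d permutations\n",
              nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters) > 0) {
    for (k in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[k, ]
      ptxt <- if (cl$p_less_than) sprintf("p < %.3g", 1 / x$n_perm)
      else sprintf("p = %.3f", cl$p)
      cat(sprintf("  %g..%g ms (size %d, mean r %.2f): %s\n",
                  cl$start_ms, cl$end_ms, cl$size, cl$mean_r, ptxt))
    }
  }
  invisible(x)
}

#' Univariate-ERP counterpart of the linkage analysis
#'
#' Correlates per-channel ERP difference waves with a behavioral/neural
#' scalar at each time point, applies Benjamini-Hochberg correction across
#' channels at each time point, and runs the shared-shuffle cluster
#' permutation per channel on the corrected p values (the FDR step is
#' recomputed inside every permutation iteration).
#'
#' @param diff_waves subjects x channels x time array of difference waves.
#' @param behavior per-subject scalar.
#' @param time time axis, ms.
#' @param channels channel labels.
#' @param q FDR level across channels (default 0.05 used as the
#'   cluster-forming threshold on corrected p).
#' @param n_perm,seed permutation settings.
#' @return list of class `univariate_linkage`: `r`, `p_raw`, `p_fdr`
#'   (channels x time), per-channel `clusters`, `null_sizes`.
#' @export
univariate_corr <- function(diff_waves, behavior, time, channels = NULL,
                            q = 0.05, n_perm = 1000, seed = 1) {
  d <- dim(diff_waves)
  n <- d[1]; nc <- d[2]; nt <- d[3]
  if (length(behavior) != n) stop("subject counts do not match")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  flat <- matrix(diff_waves, nrow = n)               # n x (nc*nt)
  obs <- pearson_cols(behavior, flat)
  r <- matrix(obs$r, nc, nt); p_raw <- matrix(obs$p, nc, nt)
  p_fdr <- matrix(apply(p_raw, 2, stats::p.adjust, method = "BH"), nc, nt)
  perms <- with_seed(derive_seed(seed, 1L), {
    vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  })
  pp <- perm_corr_p(flat, behavior, perms)           # n_perm x (nc*nt)
  null_sizes <- matrix(0L, n_perm, nc)
  for (b in seq_len(n_perm)) {
    pb <- matrix(pp[b, ], nc, nt)
    pb_fdr <- matrix(apply(pb, 2, stats::p.adjust, method = "BH"), nc, nt)
    sig <- pb_fdr < q
    null_sizes[b, ] <- apply(sig, 1, largest_run)
  }
  clusters <- lapply(seq_len(nc), function(ch) {
    cl <- logical_runs(p_fdr[ch, ] < q)
    if (nrow(cl) > 0) {
      cl$start_ms <- time[cl$start]; cl$end_ms <- time[cl$end]
      cl$size <- cl$length
      cl$p <- vapply(cl$size, function(sz) mean(null_sizes[, ch] >= sz),
                     numeric(1))
    }
    cl
  })
  names(clusters) <- channels
  rownames(r) <- rownames(p_raw) <- rownames(p_fdr) <- channels
  structure(list(r = r, p_raw = p_raw, p_fdr = p_fdr, clusters = clusters,
                 null_sizes = null_sizes, time = time, q = q, n_perm = n_perm),
            class = "univariate_linkage")
}

#' Per-subject behavioral summaries
#'
#' Mean and median reaction time over correctly performed trials that
#' required a response, and (for probabilistic cueing) the validity cost:
#' mean RT difference `invalid - valid` (uncued minus cued).
#'
#' @param trials data.frame with columns `rt` (ms, NA for trials without a
#'   required response), `correct` (logical) and `attention`
#'   (`cued`/`uncued`).
#' @return list: `mean_rt`, `median_rt`, `rt_difference`,
#'   `median_rt_difference` (NA when only one trial type has responses),
#'   `n_trials_used`.
#' @export
behavior_summaries <- function(trials) {
  stopifnot(all(c("rt", "correct", "attention") %in% names(trials)))
  ok <- trials$correct & !is.na(trials$rt)
  if (!any(ok)) stop("no correct response trials")
  rt <- trials$rt[ok]
  attn <- trials$attention[ok]
  has_both <- all(c("cued", "uncued") %in% attn)
  list(mean_rt = mean(rt), median_rt = stats::median(rt),
       rt_difference = if (has_both)
         mean(rt[attn == "uncued"]) - mean(rt[attn == "cued"]) else NA_real_,
       median_rt_difference = if (has_both)
         stats::median(rt[attn == "uncued"]) - stats::median(rt[attn == "cued"]) else NA_real_,
       n_trials_used = sum(ok))
}
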