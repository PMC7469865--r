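#' Decoder configuration
#'
#' Settings for the trial-averaged linear-SVM decoding time course. Per time
#' point, trials of each condition are split into `n_groups` equal groups,
#' each group is averaged into one multichannel pattern, patterns are
#' z-normalized across channels within each (group, condition), and a linear
#' SVM is trained/tested in a leave-one-group-out cross-validation; the whole
#' procedure is repeated `n_iterations` times with fresh random splits. Under
#' the defaults every time point aggregates
#' `2 conditions x 3 folds x 20 iterations = 120` decoding attempts.
#'
#' @param n_groups number of trial groups / CV folds (default 3).
#' @param n_iterations random re-partitions of trials (default 20).
#' @param cost SVM regularization constant (default 1; the published
#'   procedure leaves it unspecified, so the conventional default of the
#'   underlying library family is used).
#' @param smoothing_points odd moving-average window applied to the accuracy
#'   time course (default 5 = +/-40 ms at 50 Hz).
#' @param channel_subset optional label vector restricting the features
#'   (e.g., `c("F7", "F8")` for the eye-movement proxy check).
#' @param time_window optional ms pair restricting the decoded time points.
#' @param return_maps if TRUE, accumulate activation-pattern maps
#'   (classifier weights transformed by the training-pattern covariance).
#' @param seed master seed; iteration k of subject-level decoding uses a
#'   deterministic substream, so results are bit-identical under a fixed
#'   seed and independent of evaluation order.
#' @return a `decoder_config` list.
#' @export
decoder_config <- function(n_groups = 3, n_iterations = 20, cost = 1,
                           smoothing_points = 5, channel_subset = NULL,
                           time_window = NULL, return_maps = FALSE, seed = 1) {
  stopifnot(n_groups >= 2, n_iterations >= 1, smoothing_points %% 2 == 1)
  structure(list(n_groups = as.integer(n_groups),
                 n_iterations = as.integer(n_iterations), cost = cost,
                 smoothing_points = as.integer(smoothing_points),
                 channel_subset = channel_subset, time_window = time_window,
                 return_maps = isTRUE(return_maps), seed = as.integer(seed)),
            class = "decoder_config")
}

#' Randomly partition trials of each condition into equal groups
#'
#' Remainder trials (one or two per condition when the count is not evenly
#' divisible by the group count) are omitted for that iteration.
#'
#' @param condition per-trial condition labels.
#' @param n_groups number of groups.
#' @return integer vector: group index 1..n_groups per trial, NA for omitted
#'   trials.
#' @export
partition_trials <- function(condition, n_groups = 3) {
  out <- rep(NA_integer_, length(condition))
  for (cond in unique(condition)) {
    idx <- which(condition == cond)
    if (length(idx) < n_groups) stop("fewer trials than groups in ", cond)
    size <- length(idx) %/% n_groups
    keep <- sample(idx, size * n_groups)
    out[keep] <- rep(seq_len(n_groups), each = size)
  }
  out
}

#' z-normalize a channel pattern
#'
#' Centers and scales a channel vector to mean 0, unit sample standard
#' deviation (n-1 convention). Degenerate constant vectors map to all zeros
#' (avoids NaN propagation on toy inputs).
#'
#' @param v numeric channel vector.
#' @return normalized vector.
#' @export
znorm_pattern <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Group-averaged, z-normalized patterns at one time point
#'
#' Averages member trials of each (group, condition) cell into one channel
#' vector and z-normalizes it across channels within the cell.
#'
#' @param data trials x channels matrix (the time slice).
#' @param condition per-trial labels (2 levels).
#' @param assignment group index per trial from [partition_trials()].
#' @return list: `patterns` ((groups*conditions) x channels matrix),
#'   `group`, `condition` per row.
#' @export
build_patterns <- function(data, condition, assignment) {
  conds <- sort(unique(condition))
  groups <- sort(unique(assignment[!is.na(assignment)]))
  rows <- list(); grp <- integer(0); cnd <- character(0)
  for (cond in conds) {
    for (g in groups) {
      sel <- which(condition == cond & assignment == g)
      if (length(sel) == 0) stop("empty group ", g, " in ", cond)
      v <- colMeans(data[sel, , drop = FALSE])
      rows[[length(rows) + 1]] <- znorm_pattern(v)
      grp <- c(grp, g); cnd <- c(cnd, cond)
    }
  }
  list(patterns = do.call(rbind, rows), group = grp, condition = cnd)
}

# Fit a linear SVM and return the decision rule (w, rho, positive label).
# Degenerate training sets (e.g., identical patterns with opposite labels)
# fall back to a deterministic first-label rule.
fit_linear_svm <- function(X, y, cost) {
  lv <- levels(y)
  m <- tryCatch(
    e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
               type = "C-classification", fitted = FALSE),
    error = function(e) NULL)
  if (is.null(m)) return(list(w = rep(0, ncol(X)), rho = 0, pos = lv[1], fallback = TRUE))
  list(w = as.vector(crossprod(m$coefs, m$SV)), rho = m$rho, pos = m$levels[1],
       fallback = FALSE)
}

predict_linear_svm <- function(model, X, lv) {
  d <- as.vector(X %*% model$w) - model$rho
  neg <- setdiff(lv, model$pos)
  # ties on the boundary resolve deterministically to the positive label
  ifelse(d >= 0, model$pos, if (length(neg)) neg else model$pos)
}

#' Cross-validated accuracy for one set of patterns
#'
#' Leave-one-group-out: train on the patterns of all other groups, predict
#' the held-out group's two condition patterns; a prediction is correct iff
#' the predicted label equals the true condition.
#'
#' @param patterns output of [build_patterns()].
#' @param cost SVM regularization constant.
#' @param collect_maps if TRUE also return the fold-averaged activation map
#'   (training-pattern covariance times weight vector).
#' @return list: `correct` (count), `attempts`, and optionally `map`.
#' @export
crossval_accuracy_at_time <- function(patterns, cost = 1, collect_maps = FALSE) {
  P <- patterns$patterns
  y <- factor(patterns$condition)
  lv <- levels(y)
  if (length(lv) != 2) stop("exactly two conditions required")
  groups <- sort(unique(patterns$group))
  correct <- 0L; attempts <- 0L
  map <- if (collect_maps) numeric(ncol(P)) else NULL
  for (g in groups) {
    test <- patterns$group == g
    m <- fit_linear_svm(P[!test, , drop = FALSE], droplevels(y[!test]), cost)
    pred <- predict_linear_svm(m, P[test, , drop = FALSE], lv)
    correct <- correct + sum(pred == as.character(y[test]))
    attempts <- attempts + sum(test)
    if (collect_maps && !m$fallback) {
      # activation pattern: covariance of the normalized training features
      # times the weight vector, sign-aligned to the first condition level
      S <- stats::cov(P[!test, , drop = FALSE])
      a <- as.vector(S %*% m$w)
      if (m$pos != lv[1]) a <- -a
      map <- map + a
    }
  }
  out <- list(correct = correct, attempts = attempts)
  if (collect_maps) out$map <- map / length(groups)
  out
}

#' Trial-averaged SVM decoding time course
#'
#' The full per-subject decoding procedure: for each time point, repeated
#' random partitioning of each condition's trials into groups, group
#' averaging into multichannel patterns, per-pattern z-normalization across
#' channels, linear-SVM cross-validation, aggregation over conditions,
#' folds and iterations, and moving-average smoothing of the resulting
#' accuracy time course.
#'
#' @param epochs a preprocessed [epochset()] (8 Hz low-passed, trimmed,
#'   downsampled) with exactly two condition labels.
#' @param config a [decoder_config()].
#' @return list of class `decoding_timecourse`: `time` (ms), `accuracy`,
#'   `accuracy_smoothed`, `n_attempts` per point, optionally `maps`
#'   (channels x time activation patterns), plus bookkeeping (`channels`,
#'   `subject_id`, `config`).
#' @export
decode_timecourse <- function(epochs, config = decoder_config()) {
  chans <- if (is.null(config$channel_subset)) eeg_channels(epochs) else config$channel_subset
  ci <- match(chans, epochs$channels)
  if (anyNA(ci)) stop("missing channel(s): ",
                      paste(chans[is.na(ci)], collapse = ", "))
  ti <- if (is.null(config$time_window)) seq_along(epochs$time) else
    which(epochs$time >= config$time_window[1] & epochs$time <= config$time_window[2])
  if (length(ti) == 0) stop("empty decoding time window")
  cond <- epochs$trials$condition
  if (length(unique(cond)) != 2) stop("exactly two conditions required")
  nt <- length(ti)
  correct <- numeric(nt); attempts <- numeric(nt)
  maps <- if (config$return_maps) matrix(0, length(ci), nt) else NULL
  dat <- epochs$data[, ci, ti, drop = FALSE]
  for (it in seq_len(config$n_iterations)) {
    assignment <- with_seed(derive_seed(config$seed, it),
                            partition_trials(cond, config$n_groups))
    # group-average all time points at once for this partition
    cell <- interaction(cond, assignment, drop = TRUE)
    keep <- !is.na(assignment)
    flat <- matrix(dat[keep, , , drop = FALSE], nrow = sum(keep))
    gm <- rowsum(flat, group = droplevels(cell[keep]))
    gm <- gm / as.vector(table(droplevels(cell[keep])))
    info <- do.call(rbind, strsplit(rownames(gm), ".", fixed = TRUE))
    pat_cond <- info[, 1]; pat_group <- as.integer(info[, 2])
    gm_arr <- array(gm, dim = c(nrow(gm), length(ci), nt))
    for (t in seq_len(nt)) {
      P <- gm_arr[, , t, drop = TRUE]
      if (is.null(dim(P))) P <- matrix(P, nrow = nrow(gm))
      P <- t(apply(P, 1, znorm_pattern))
      res <- crossval_accuracy_at_time(
        list(patterns = P, group = pat_group, condition = pat_cond),
        cost = config$cost, collect_maps = config$return_maps)
      correct[t] <- correct[t] + res$correct
      attempts[t] <- attempts[t] + res$attempts
      if (config$return_maps) maps[, t] <- maps[, t] + res$map
    }
  }
  acc <- correct / attempts
  out <- list(time = epochs$time[ti], accuracy = acc,
              accuracy_smoothed = smooth_timecourse(acc, config$smoothing_points),
              n_attempts = attempts, channels = chans,
              subject_id = epochs$subject_id, config = config)
  if (config$return_maps) {
    out$maps <- maps / config$n_iterations
    rownames(out$maps) <- chans
  }
  class(out) <- "decoding_timecourse"
  out
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> subject %s: %d time points (%g..%g ms), mean accuracy %.3f\n",
              x$subject_id, length(x$time), min(x$time), max(x$time),
              mean(x$accuracy)))
  invisible(x)
}

#' Channel-subset decoding (eye-movement proxy check)
#'
#' Runs the identical decoding pipeline restricted to a channel subset;
#' with the frontal pair F7/F8 this serves as the residual ocular-confound
#' check: above-chance decoding from these two channels, especially late in
#' the cue-target interval, indicates decodable eye-movement artifacts.
#'
#' @param epochs a preprocessed [epochset()].
#' @param labels channel labels (default `c("F7", "F8")`).
#' @param config a [decoder_config()]; its `channel_subset` is overridden.
#' @return a `decoding_timecourse`.
#' @export
channel_subset_decode <- function(epochs, labels = c("F7", "F8"),
                                  config = decoder_config()) {
  config$channel_subset <- labels
  decode_timecourse(epochs, config)
}

#' Window-averaged activation maps
#'
#' Averages per-timepoint activation patterns over reporting windows.
#'
#' @param tc a `decoding_timecourse` computed with `return_maps = TRUE`.
#' @param windows list of ms pairs.
#' @return channels x windows matrix.
#' @export
window_average_maps <- function(tc, windows) {
  if (is.null(tc$maps)) stop("timecourse has no activation maps")
  out <- sapply(windows, function(w) {
    sel <- tc$time >= w[1] & tc$time < w[2]
    if (!any(sel)) stop("empty map window")
    rowMeans(tc$maps[, sel, drop = FALSE])
  })
  rownames(out) <- rownames(tc$maps)
  colnames(out) <- vapply(windows, function(w) paste0(w[1], "-", w[2]), "")
  out
}
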