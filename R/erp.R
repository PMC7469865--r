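#' Condition-averaged ERPs
#'
#' Arithmetic mean across trials of one condition. Averaging and baseline
#' correction are both linear, so their order does not matter.
#'
#' @param epochs an [epochset()].
#' @param condition condition label to average (must have >= 1 trial).
#' @param trials optional extra logical/integer trial filter applied before
#'   averaging (e.g., retained trials from [screen_epochs()]).
#' @return list of class `erp`: `wave` (channels x samples matrix, uV),
#'   `time`, `channels`, `n_trials`, `condition`.
#' @export
average_condition <- function(epochs, condition, trials = NULL) {
  sel <- epochs$trials$condition == condition
  if (!is.null(trials)) {
    keep <- rep(FALSE, n_trials(epochs)); keep[trials] <- TRUE
    sel <- sel & keep
  }
  if (!any(sel)) stop("no trials in condition ", condition)
  wave <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  structure(list(wave = wave, time = epochs$time, channels = epochs$channels,
                 n_trials = sum(sel), condition = condition),
            class = "erp")
}

#' Default posterior N1 regions of interest
#'
#' The 3-channel-per-hemisphere variant for reduced montages and the
#' 7-channel variant for dense montages, selected by montage size.
#'
#' @param channels channel labels of the recording.
#' @return list with `left` and `right` character vectors.
#' @export
default_n1_roi <- function(channels) {
  dense <- list(left = c("P1", "P3", "P5", "P7", "PO3", "PO7", "O1"),
                right = c("P2", "P4", "P6", "P8", "PO4", "PO8", "O2"))
  small <- list(left = c("P3", "P7", "O1"), right = c("P4", "P8", "O2"))
  if (all(unlist(dense) %in% channels)) dense else small
}

#' Measure the target-evoked N1 and its attention modulation
#'
#' For each attention condition, averages the ERP voltage over the N1 window
#' in the region of interest contralateral to the target (left-hemisphere
#' ROI for right-field targets and vice versa), then averages the two sides
#' with equal weight. The modulation is `cued - uncued` with the negative
#' sign maintained: a stronger (more negative) N1 for cued targets yields a
#' negative modulation.
#'
#' @param epochs a target-locked [epochset()] whose trial table carries
#'   `attention` (`cued`/`uncued`) and `target_side` (`left`/`right`).
#' @param roi list with `left`/`right` channel vectors (default chosen by
#'   montage size via [default_n1_roi()]).
#' @param window N1 measurement window in ms; both endpoints inclusive on
#'   the sample grid (conventional mean-amplitude semantics). Default
#'   `c(170, 210)`.
#' @param trials optional trial filter (retained indices).
#' @return list of class `n1_measure`: per-condition amplitudes (uV),
#'   `modulation` (uV, cued - uncued), ROI and window used.
#' @export
measure_n1 <- function(epochs, roi = default_n1_roi(epochs$channels),
                       window = c(170, 210), trials = NULL) {
  tr <- epochs$trials
  if (!all(c("attention", "target_side") %in% names(tr)))
    stop("trials must carry attention and target_side")
  for (side in c("left", "right")) {
    miss <- setdiff(roi[[side]], epochs$channels)
    if (length(miss) > 0) stop("ROI channel(s) missing: ", paste(miss, collapse = ", "))
  }
  keep <- rep(TRUE, n_trials(epochs))
  if (!is.null(trials)) { keep <- rep(FALSE, n_trials(epochs)); keep[trials] <- TRUE }
  sel_t <- epochs$time >= window[1] & epochs$time <= window[2]
  if (!any(sel_t)) stop("N1 window contains no samples")
  amp <- matrix(NA_real_, 2, 2,
                dimnames = list(c("cued", "uncued"), c("left", "right")))
  for (attn in c("cued", "uncued")) {
    for (side in c("left", "right")) {
      contra <- if (side == "left") roi$right else roi$left
      ci <- match(contra, epochs$channels)
      sel <- keep & tr$attention == attn & tr$target_side == side
      if (!any(sel)) stop("no trials for ", attn, " targets on the ", side)
      amp[attn, side] <- mean(epochs$data[sel, ci, sel_t])
    }
  }
  by_cond <- rowMeans(amp)  # equal weighting of the two sides
  structure(list(amplitude = by_cond, by_side = amp,
                 modulation = unname(by_cond["cued"] - by_cond["uncued"]),
                 roi = roi, window = window),
            class = "n1_measure")
}

#' @export
print.n1_measure <- function(x, ...) {
  cat(sprintf("<n1_measure> cued %.2f uV, uncued %.2f uV, modulation %.2f uV\n",
              x$amplitude["cued"], x$amplitude["uncued"], x$modulation))
  invisible(x)
}

#' Condition difference wave
#'
#' Elementwise `a - b` of two condition-averaged ERPs.
#'
#' @param erp_a,erp_b `erp` objects from [average_condition()] with matching
#'   channels and time axes.
#' @return channels x samples matrix (uV).
#' @export
difference_wave <- function(erp_a, erp_b) {
  if (!identical(dim(erp_a$wave), dim(erp_b$wave)))
    stop("ERP shapes do not match")
  if (!isTRUE(all.equal(erp_a$time, erp_b$time)))
    stop("time axes do not match")
  erp_a$wave - erp_b$wave
}
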