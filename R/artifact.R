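#' Trial-rejection criteria
#'
#' The four moving-window screening criteria used on epoched data:
#' peak-to-peak (200 ms window, 50 ms step, 150 uV) on any EEG channel;
#' absolute voltage (100 uV) anywhere in the epoch on any EEG channel; an
#' HEOG step function (400 ms window, 10 ms step, 40 uV: difference in mean
#' amplitude between the two window halves, sensitive to small saccades);
#' and a VEOG peak-to-peak blink detector (200 ms window, 10 ms step, 50 uV)
#' restricted to the -200..200 ms interval around stimulus presentation.
#' Window widths/steps given in ms are converted to samples with
#' `max(1, round())`; only windows lying fully inside the epoch (or scan
#' interval) are evaluated.
#'
#' @param p2p_window,p2p_step,p2p_threshold peak-to-peak criterion (ms, ms, uV).
#' @param abs_threshold absolute-voltage criterion (uV).
#' @param heog_step_window,heog_step_step,heog_step_threshold HEOG step
#'   criterion (ms, ms, uV).
#' @param veog_window,veog_step,veog_threshold,veog_scan_interval VEOG blink
#'   criterion (ms, ms, uV, ms pair).
#' @return a `rejection_criteria` list.
#' @export
rejection_criteria <- function(p2p_window = 200, p2p_step = 50,
                               p2p_threshold = 150, abs_threshold = 100,
                               heog_step_window = 400, heog_step_step = 10,
                               heog_step_threshold = 40,
                               veog_window = 200, veog_step = 10,
                               veog_threshold = 50,
                               veog_scan_interval = c(-200, 200)) {
  cr <- list(p2p_window = p2p_window, p2p_step = p2p_step,
             p2p_threshold = p2p_threshold, abs_threshold = abs_threshold,
             heog_step_window = heog_step_window,
             heog_step_step = heog_step_step,
             heog_step_threshold = heog_step_threshold,
             veog_window = veog_window, veog_step = veog_step,
             veog_threshold = veog_threshold,
             veog_scan_interval = veog_scan_interval)
  if (any(unlist(cr[c(1:4, 5:7, 8:10)]) <= 0)) stop("criteria must be positive")
  class(cr) <- "rejection_criteria"
  cr
}

# Start indices of full windows of length w samples stepping s samples
# within n samples.
window_starts <- function(n, w, s) {
  if (w > n) stop("window longer than the epoch")
  seq(1L, n - w + 1L, by = s)
}

ms_to_samples <- function(ms, sfreq) max(1L, as.integer(round(ms * sfreq / 1000)))

#' Moving-window peak-to-peak rejection
#'
#' Flags a trial when any full window on any selected channel has
#' `max - min > threshold`.
#'
#' @param epochs an [epochset()].
#' @param window,step window width and step, ms.
#' @param threshold peak-to-peak threshold, uV.
#' @param channels channel labels to scan (default: all EEG channels).
#' @return logical vector, one flag per trial.
#' @export
moving_p2p_reject <- function(epochs, window = 200, step = 50, threshold = 150,
                              channels = eeg_channels(epochs)) {
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("missing channel(s)")
  w <- ms_to_samples(window, epochs$sfreq)
  s <- ms_to_samples(step, epochs$sfreq)
  n <- dim(epochs$data)[3]
  starts <- window_starts(n, w, s)
  flags <- rep(FALSE, dim(epochs$data)[1])
  for (st in starts) {
    seg <- epochs$data[, ci, st:(st + w - 1L), drop = FALSE]
    p2p <- apply(seg, c(1, 2), function(v) max(v) - min(v))
    flags <- flags | apply(p2p > threshold, 1, any)
  }
  flags
}

#' Absolute-voltage rejection
#'
#' Flags a trial when the absolute voltage at any sample of any EEG channel
#' exceeds the threshold.
#'
#' @param epochs an [epochset()].
#' @param threshold uV (default 100).
#' @param channels channel labels (default: all EEG channels).
#' @return logical vector per trial.
#' @export
abs_threshold_reject <- function(epochs, threshold = 100,
                                 channels = eeg_channels(epochs)) {
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("missing channel(s)")
  apply(abs(epochs$data[, ci, , drop = FALSE]) > threshold, 1, any)
}

#' HEOG step-function rejection (small eye movements)
#'
#' For each full window, compares the mean of the first half with the mean of
#' the second half; flags the trial if the absolute difference exceeds the
#' threshold on the HEOG channel.
#'
#' @param epochs an [epochset()] containing an `HEOG` channel.
#' @param window,step,threshold ms, ms, uV (defaults 400, 10, 40).
#' @return logical vector per trial.
#' @export
heog_step_reject <- function(epochs, window = 400, step = 10, threshold = 40) {
  ci <- match("HEOG", epochs$channels)
  if (is.na(ci)) stop("HEOG channel not present")
  w <- ms_to_samples(window, epochs$sfreq)
  if (w %% 2L == 1L) w <- w + 1L  # halves must be equal
  s <- ms_to_samples(step, epochs$sfreq)
  n <- dim(epochs$data)[3]
  starts <- window_starts(n, w, s)
  half <- w %/% 2L
  x <- epochs$data[, ci, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = dim(epochs$data)[1])
  flags <- rep(FALSE, nrow(x))
  for (st in starts) {
    m1 <- rowMeans(x[, st:(st + half - 1L), drop = FALSE])
    m2 <- rowMeans(x[, (st + half):(st + w - 1L), drop = FALSE])
    flags <- flags | (abs(m2 - m1) > threshold)
  }
  flags
}

#' VEOG blink rejection around stimulus presentation
#'
#' Moving-window peak-to-peak detector on the VEOG channel, applied only to
#' windows fully inside the scan interval around stimulus onset.
#'
#' @param epochs an [epochset()] containing a `VEOG` channel.
#' @param window,step,threshold ms, ms, uV (defaults 200, 10, 50).
#' @param scan_interval ms pair (default `c(-200, 200)`).
#' @return logical vector per trial.
#' @export
veog_blink_reject <- function(epochs, window = 200, step = 10, threshold = 50,
                              scan_interval = c(-200, 200)) {
  ci <- match("VEOG", epochs$channels)
  if (is.na(ci)) stop("VEOG channel not present")
  sel <- which(epochs$time >= scan_interval[1] & epochs$time <= scan_interval[2])
  if (length(sel) == 0) stop("scan interval contains no samples")
  w <- ms_to_samples(window, epochs$sfreq)
  s <- ms_to_samples(step, epochs$sfreq)
  x <- epochs$data[, ci, sel, drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = dim(epochs$data)[1])
  starts <- window_starts(ncol(x), w, s)
  flags <- rep(FALSE, nrow(x))
  for (st in starts) {
    seg <- x[, st:(st + w - 1L), drop = FALSE]
    flags <- flags | ((apply(seg, 1, max) - apply(seg, 1, min)) > threshold)
  }
  flags
}

#' Screen epochs with all four rejection criteria
#'
#' Criteria are order-independent; the final rejection mask is their union.
#' EOG-based criteria are applied to the (uncorrected) HEOG/VEOG channels
#' carried alongside the EEG.
#'
#' @param epochs an [epochset()] with HEOG/VEOG channels.
#' @param criteria a [rejection_criteria()].
#' @return a `rejection_report`: per-trial logical flags per criterion
#'   (`flags`), the union (`rejected`), retained trial indices (`retained`)
#'   and per-condition rejection rates in percent (`rates`).
#' @export
screen_epochs <- function(epochs, criteria = rejection_criteria()) {
  cr <- criteria
  flags <- cbind(
    p2p = moving_p2p_reject(epochs, cr$p2p_window, cr$p2p_step, cr$p2p_threshold),
    abs = abs_threshold_reject(epochs, cr$abs_threshold),
    heog_step = heog_step_reject(epochs, cr$heog_step_window,
                                 cr$heog_step_step, cr$heog_step_threshold),
    veog_blink = veog_blink_reject(epochs, cr$veog_window, cr$veog_step,
                                   cr$veog_threshold, cr$veog_scan_interval))
  rejected <- apply(flags, 1, any)
  cond <- epochs$trials$condition
  rates <- tapply(rejected, cond, function(z) 100 * mean(z))
  structure(list(flags = flags, rejected = rejected,
                 retained = which(!rejected),
                 rates = rates, criteria = criteria),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %d/%d trials rejected (%.1f%%)\n",
              sum(x$rejected), length(x$rejected), 100 * mean(x$rejected)))
  for (nm in names(x$rates)) cat(sprintf("  %s: %.1f%%\n", nm, x$rates[nm]))
  invisible(x)
}

#' Write a rejection report to disk
#'
#' One CSV row per trial with one column per criterion, plus a JSON summary
#' of per-condition rejection rates.
#'
#' @param report a `rejection_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_rejection_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(trial = seq_along(report$rejected), report$flags,
                   rejected = report$rejected)
  data.table::fwrite(df, file.path(dir, "rejection_flags.csv"))
  jsonlite::write_json(as.list(report$rates), file.path(dir, "rejection_rates.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Residual horizontal eye-movement report
#'
#' Grand average over retained trials of the HEOG difference between the two
#' cue conditions during the cue-target interval, with an approximate
#' conversion to degrees of gaze. A residual below ~2 uV (~0.2 deg at the
#' default conversion factor) indicates that systematic cue-related eye
#' movements cannot explain lateralized decodability.
#'
#' @param epochs_list list of cue-locked [epochset()]s (one per subject),
#'   ideally after artifact screening.
#' @param interval ms pair over which to average (default `c(0, 1200)`).
#' @param uv_per_degree HEOG sensitivity; ~16 uV per degree of horizontal
#'   gaze is the conventional literature value, exposed here as an
#'   assumption.
#' @return list with `difference_uv` (grand-average cue_left - cue_right
#'   HEOG), `degrees`, and per-subject values.
#' @export
heog_residual_report <- function(epochs_list, interval = c(0, 1200),
                                 uv_per_degree = 16) {
  if (inherits(epochs_list, "epochset")) epochs_list <- list(epochs_list)
  per_subj <- vapply(epochs_list, function(ep) {
    ci <- match("HEOG", ep$channels)
    if (is.na(ci)) stop("HEOG channel not present")
    sel <- ep$time >= interval[1] & ep$time < interval[2]
    cond <- ep$trials$condition
    if (!all(c("cue_left", "cue_right") %in% cond))
      stop("both cue conditions must be present")
    l <- mean(ep$data[cond == "cue_left", ci, sel])
    r <- mean(ep$data[cond == "cue_right", ci, sel])
    l - r
  }, numeric(1))
  diff_uv <- mean(per_subj)
  list(difference_uv = diff_uv, degrees = diff_uv / uv_per_degree,
       per_subject_uv = per_subj, uv_per_degree = uv_per_degree)
}
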