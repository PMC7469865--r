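#' Epoched multichannel EEG container
#'
#' An `epochset` holds a trials x channels x samples array of voltages (uV)
#' together with its time axis, sampling rate, channel labels and per-trial
#' metadata. The time axis is the half-open sample grid `[start, end)`: an
#' epoch declared as -1000..1400 ms at 250 Hz has 600 samples at
#' -1000, -996, ..., 1396 ms. This convention makes the standard decoding
#' windows come out at exactly 100 (cue, -800..1200 ms at 50 Hz) and 55
#' (target, -300..800 ms) feature time points.
#'
#' @param data numeric array `[trials, channels, samples]`, microvolts.
#' @param time numeric vector of sample times in ms (strictly increasing,
#'   uniform spacing `1000/sfreq`).
#' @param sfreq sampling rate in Hz.
#' @param channels character vector of channel labels (unique). Labels
#'   `HEOG`/`VEOG` are treated as ocular channels and excluded from EEG-wide
#'   operations such as decoding and voltage-threshold screening.
#' @param trials data.frame of per-trial metadata with at least a `condition`
#'   column; target-locked sets carry `cue_side`, `target_side`, `rt`,
#'   `correct`.
#' @param subject_id subject identifier string.
#' @param event locking event label (`"cue"` or `"target"`).
#' @return an object of class `epochset`.
#' @export
epochset <- function(data, time, sfreq, channels,
                     trials = data.frame(condition = rep(NA_character_, dim(data)[1])),
                     subject_id = "s01", event = "cue") {
  if (length(dim(data)) != 3) stop("data must be a trials x channels x samples array")
  if (dim(data)[2] != length(channels)) stop("channel count mismatch")
  if (dim(data)[3] != length(time)) stop("sample count mismatch")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (nrow(trials) != dim(data)[1]) stop("trials metadata row count mismatch")
  if (!"condition" %in% names(trials)) stop("trials must have a 'condition' column")
  if (anyNA(time) || anyNA(data)) stop("time and data must not contain NA")
  dt <- diff(time)
  if (length(dt) > 0) {
    if (any(dt <= 0)) stop("time vector must be strictly increasing")
    if (max(abs(dt - 1000 / sfreq)) > 1e-6) stop("time spacing must equal 1000/sfreq ms")
  }
  structure(list(data = data, time = as.numeric(time), sfreq = sfreq,
                 channels = as.character(channels), trials = trials,
                 subject_id = subject_id, event = event),
            class = "epochset")
}

#' @export
print.epochset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochset> subject %s, %s-locked: %d trials x %d channels x %d samples\n",
              x$subject_id, x$event, d[1], d[2], d[3]))
  cat(sprintf("  time %g..%g ms @ %g Hz\n", min(x$time), max(x$time), x$sfreq))
  cat("  conditions:", paste(sprintf("%s=%d", names(table(x$trials$condition)),
                                     table(x$trials$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epochset <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

#' EEG (non-ocular) channel labels of an epochset
#' @param x an `epochset`.
#' @return character vector of channel labels excluding HEOG/VEOG.
#' @export
eeg_channels <- function(x) setdiff(x$channels, c("HEOG", "VEOG"))

#' Subset an epochset
#'
#' @param x an `epochset`.
#' @param trials integer/logical trial index (optional).
#' @param channels character labels or index (optional).
#' @param time_window ms pair; keeps samples with `start <= t < end` (optional).
#' @return a new `epochset`.
#' @export
subset_epochs <- function(x, trials = NULL, channels = NULL, time_window = NULL) {
  ti <- if (is.null(trials)) seq_len(dim(x$data)[1]) else trials
  if (is.null(channels)) {
    ci <- seq_along(x$channels)
  } else if (is.character(channels)) {
    ci <- match(channels, x$channels)
    if (anyNA(ci)) stop("missing channel(s): ",
                        paste(channels[is.na(ci)], collapse = ", "))
  } else ci <- channels
  si <- if (is.null(time_window)) seq_along(x$time) else
    which(x$time >= time_window[1] & x$time < time_window[2])
  if (length(si) == 0) stop("empty time window")
  epochset(x$data[ti, ci, si, drop = FALSE], x$time[si], x$sfreq,
           x$channels[ci], x$trials[ti, , drop = FALSE], x$subject_id, x$event)
}

#' Write / read an epochset as a plain-text directory
#'
#' Layout: `meta.json` (time axis, sampling rate, channels, subject, event),
#' `trials.csv` (per-trial metadata) and `data.csv` (one row per
#' trial-channel, samples across columns).
#'
#' @param x an `epochset`.
#' @param dir directory to create/read.
#' @return `write_epochset` returns `dir` invisibly; `read_epochset` returns
#'   an `epochset`.
#' @export
write_epochset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(time = x$time, sfreq = x$sfreq, channels = x$channels,
               subject_id = x$subject_id, event = x$event, dims = dim(x$data))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(x$trials, file.path(dir, "trials.csv"))
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(flat), file.path(dir, "data.csv"))
  invisible(dir)
}

#' @rdname write_epochset
#' @param dir directory previously written by `write_epochset`.
#' @export
read_epochset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  trials <- as.data.frame(data.table::fread(file.path(dir, "trials.csv")))
  flat <- as.matrix(data.table::fread(file.path(dir, "data.csv")))
  d <- meta$dims
  data <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  epochset(data, meta$time, meta$sfreq, meta$channels, trials,
           meta$subject_id, meta$event)
}
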