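#' Least-squares linear-phase FIR design
#'
#' Designs a symmetric FIR filter by dense-grid least squares against a
#' piecewise-constant desired amplitude response (the design family behind
#' the classic EEG filtering routines). The standard order rule for the
#' pre-decoding low-pass is `3 * floor(srate / locutoff)` (93 taps + 1 at
#' 250 Hz / 8 Hz).
#'
#' @param order filter order (number of taps minus one).
#' @param bands matrix with rows `(f_lo, f_hi, amplitude)` in Hz covering the
#'   bands that constrain the fit; transition regions are left free.
#' @param sfreq sampling rate, Hz.
#' @return numeric vector of `order + 1` symmetric coefficients.
#' @export
fir_ls_design <- function(order, bands, sfreq) {
  order <- as.integer(order)
  if (order < 1) stop("FIR order must be a positive integer")
  ny <- sfreq / 2
  bands <- rbind(bands)
  if (any(bands[, 1:2] < 0) || any(bands[, 1:2] > ny))
    stop("band edges must lie within [0, Nyquist]")
  n_tap <- order + 1L
  grid <- list(); target <- list()
  for (i in seq_len(nrow(bands))) {
    ng <- max(16L, ceiling((bands[i, 2] - bands[i, 1]) / ny * 8L * n_tap))
    g <- seq(bands[i, 1], bands[i, 2], length.out = ng)
    grid[[i]] <- g; target[[i]] <- rep(bands[i, 3], ng)
  }
  w <- pi * unlist(grid) / ny          # radian frequency on [0, pi]
  d <- unlist(target)
  if (n_tap %% 2L == 1L) {             # type I: h symmetric, odd length
    M <- (n_tap - 1L) / 2L
    B <- cbind(1, if (M > 0) cos(outer(w, 1:M)) else NULL)
    a <- qr.solve(B, d)
    h <- c(rev(a[-1] / 2), a[1], a[-1] / 2)
  } else {                             # type II: even length
    M <- n_tap / 2L
    B <- cos(outer(w, (1:M) - 0.5))
    b <- qr.solve(B, d)
    h <- c(rev(b / 2), b / 2)
  }
  h
}

# Frequency response (complex) of an FIR filter at frequencies f (Hz).
fir_response <- function(h, f, sfreq) {
  k <- seq_along(h) - 1
  vapply(f, function(fi) sum(h * exp(-2i * pi * fi * k / sfreq)), complex(1))
}

# Zero-phase FIR filtering of the columns of a matrix via FFT convolution
# with the forward-backward kernel conv(h, rev(h)). Signals are zero-padded;
# the epoch ends are trimmed downstream, which is why epochs are extracted
# longer than the analysis windows.
fir_filtfilt_mat <- function(x, h) {
  n <- nrow(x)
  g <- stats::convolve(h, h, type = "open")  # conv(h, rev(h)): zero phase
  L <- stats::nextn(n + length(g) - 1)
  G <- stats::fft(c(g, rep(0, L - length(g))))
  X <- stats::mvfft(rbind(x, matrix(0, L - n, ncol(x))))
  y <- Re(stats::mvfft(X * G, inverse = TRUE)) / L
  lag <- length(h) - 1L                      # group delay of the full kernel
  y[(lag + 1):(lag + n), , drop = FALSE]
}

# Apply a zero-phase FIR to every trial/channel of an epochset.
apply_fir_epochs <- function(epochs, h, channels = NULL) {
  d <- dim(epochs$data)
  ci <- if (is.null(channels)) seq_len(d[2]) else match(channels, epochs$channels)
  x <- matrix(aperm(epochs$data[, ci, , drop = FALSE], c(3, 1, 2)),
              nrow = d[3])
  y <- fir_filtfilt_mat(x, h)
  out <- epochs
  out$data[, ci, ] <- aperm(array(y, dim = c(d[3], d[1], length(ci))),
                            c(2, 3, 1))
  out
}

#' Zero-phase Butterworth band-pass of a continuous recording
#'
#' Order-2 Butterworth (12 dB/oct roll-off) applied forward-backward for
#' zero phase shift; removes DC and slow drifts below the low edge.
#'
#' @param x numeric matrix, samples x channels (continuous recording), or a
#'   vector.
#' @param sfreq sampling rate, Hz.
#' @param band length-2 numeric, band edges in Hz (default `c(0.1, 40)`).
#' @param order per-pass Butterworth order (default 2).
#' @return filtered data, same shape.
#' @export
bandpass_continuous <- function(x, sfreq, band = c(0.1, 40), order = 2) {
  ny <- sfreq / 2
  if (any(band <= 0) || any(band >= ny)) stop("band edges must lie in (0, Nyquist)")
  bf <- signal::butter(order, band / ny, type = "pass")
  filt_cols(x, function(v) signal::filtfilt(bf, v))
}

#' Parks-McClellan notch filter for line noise
#'
#' Equiripple FIR band-stop (stopband `freq` +/- `half_width` Hz), applied
#' zero-phase. The published procedure states only the notch frequency; the
#' stopband width, transition width and order are exposed here with
#' documented defaults.
#'
#' @param x samples x channels matrix or vector.
#' @param sfreq sampling rate, Hz.
#' @param freq notch frequency, Hz (default 50).
#' @param half_width stopband half-width, Hz (default 1).
#' @param trans transition width, Hz (default 3).
#' @param order FIR order (default 200).
#' @return filtered data, same shape.
#' @export
notch_continuous <- function(x, sfreq, freq = 50, half_width = 1, trans = 3,
                             order = 200) {
  ny <- sfreq / 2
  if (freq >= ny) stop("notch frequency must be below Nyquist")
  f <- c(0, freq - half_width - trans, freq - half_width,
         freq + half_width, freq + half_width + trans, ny) / ny
  b <- signal::remez(n = order, f = f, a = c(1, 1, 0, 0, 1, 1))
  filt_cols(x, NULL, fir = b)
}

filt_cols <- function(x, fun, fir = NULL) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  if (!is.null(fir)) {
    ym <- fir_filtfilt_mat(xm, fir)
  } else {
    ym <- apply(xm, 2, fun)
  }
  if (vec) as.vector(ym) else ym
}

#' 8 Hz low-pass of epoched data before decoding
#'
#' Two-way (zero-phase) least-squares FIR low-pass with the order rule
#' `3 * floor(sfreq / cutoff)`; at 250 Hz and 8 Hz the order is 93. Applied
#' to epoched data before averaging and decoding so the decoded features are
#' ERP activity rather than alpha-band oscillations.
#'
#' @param epochs an [epochset()].
#' @param cutoff low-pass edge, Hz (default 8).
#' @param trans relative transition width (default 0.25: stopband starts at
#'   `cutoff * (1 + trans)`).
#' @return a filtered `epochset`, same shape.
#' @export
lowpass_epochs_8hz <- function(epochs, cutoff = 8, trans = 0.25) {
  order <- 3L * floor(epochs$sfreq / cutoff)
  if (dim(epochs$data)[3] < 3 * order)
    stop("epochs too short for the FIR order (need >= 3x the order in samples)")
  ny <- epochs$sfreq / 2
  h <- fir_ls_design(order,
                     rbind(c(0, cutoff, 1), c(cutoff * (1 + trans), ny, 0)),
                     epochs$sfreq)
  apply_fir_epochs(epochs, h)
}

#' Trim filter edges and downsample to the decoding rate
#'
#' Removes `trim_ms` from both ends of the epoch (minimizing filter edge
#' artifacts) and decimates to `target_sfreq` by keeping every
#' `sfreq / target_sfreq`-th sample; the pre-decoding 8 Hz low-pass serves as
#' the anti-alias step. On the half-open sample grid the standard cue window
#' (-1000..1400 ms trimmed to -800..1200 ms at 50 Hz) yields exactly 100
#' feature time points and the target window (-500..1000 to -300..800 ms)
#' exactly 55.
#'
#' @param epochs an [epochset()].
#' @param trim_ms ms removed from each end (default 200).
#' @param target_sfreq output rate, Hz (default 50; must divide `sfreq`).
#' @return a trimmed, downsampled `epochset`.
#' @export
trim_and_downsample <- function(epochs, trim_ms = 200, target_sfreq = 50) {
  if (epochs$sfreq %% target_sfreq != 0)
    stop("target_sfreq must divide the sampling rate")
  span <- max(epochs$time) - min(epochs$time)
  if (2 * trim_ms > span) stop("trim longer than the epoch allows")
  keep <- epochs$time >= (min(epochs$time) + trim_ms) &
    epochs$time < (max(epochs$time) + 1000 / epochs$sfreq - trim_ms)
  idx <- which(keep)
  step <- as.integer(epochs$sfreq / target_sfreq)
  idx <- idx[seq(1, length(idx), by = step)]
  out <- epochs
  out$data <- epochs$data[, , idx, drop = FALSE]
  out$time <- epochs$time[idx]
  out$sfreq <- target_sfreq
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (half-open `[start, end)` on the sample grid; the conventional
#' pre-stimulus window is -200..0 ms).
#'
#' @param epochs an [epochset()].
#' @param window ms pair (default `c(-200, 0)`).
#' @return a baseline-corrected `epochset`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  sel <- epochs$time >= window[1] & epochs$time < window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - array(base, dim = dim(epochs$data))
  out
}

#' Collapse target trials across visual fields into cued vs uncued
#'
#' Left targets preceded by left cues and right targets preceded by right
#' cues become `cued_target`; the crossed pairings become `uncued_target`.
#' Trial counts are conserved.
#'
#' @param epochs a target-locked [epochset()] whose trial table carries
#'   `target_side` and `cue_side`.
#' @return an `epochset` with `condition` relabeled to
#'   `{cued_target, uncued_target}`.
#' @export
collapse_target_conditions <- function(epochs) {
  tr <- epochs$trials
  if (!all(c("target_side", "cue_side") %in% names(tr)))
    stop("trials must carry target_side and cue_side")
  out <- epochs
  out$trials$condition <- ifelse(tr$target_side == tr$cue_side,
                                 "cued_target", "uncued_target")
  out
}

#' Alpha-band power features
#'
#' Band-passes each trial/channel to the alpha band, computes the squared
#' analytic-signal amplitude (nonnegative power envelope), applies an
#' explicit 20 Hz anti-alias low-pass (the envelope of alpha content exceeds
#' the 8 Hz pre-decoding filter by design) and then trims/downsamples like
#' the voltage features. Used as the oscillatory control analysis for the
#' voltage-pattern decoding.
#'
#' @param epochs an [epochset()] at its native rate.
#' @param band alpha band edges, Hz (default `c(8, 13)`).
#' @param trim_ms,target_sfreq passed to [trim_and_downsample()].
#' @return an `epochset` of power features (uV^2).
#' @export
alpha_power_features <- function(epochs, band = c(8, 13), trim_ms = 200,
                                 target_sfreq = 50) {
  ny <- epochs$sfreq / 2
  if (any(band <= 0) || any(band >= ny)) stop("band must lie in (0, Nyquist)")
  order <- 3L * floor(epochs$sfreq / band[1])
  h <- fir_ls_design(order, rbind(c(0, band[1] - 3, 0),
                                  c(band[1], band[2], 1),
                                  c(band[2] + 3, ny, 0)), epochs$sfreq)
  filt <- apply_fir_epochs(epochs, h)
  d <- dim(filt$data)
  x <- matrix(aperm(filt$data, c(3, 1, 2)), nrow = d[3])
  env2 <- analytic_power_mat(x)
  out <- filt
  out$data <- aperm(array(env2, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  h_aa <- fir_ls_design(3L * floor(epochs$sfreq / 20),
                        rbind(c(0, 20, 1), c(25, ny, 0)), epochs$sfreq)
  out <- apply_fir_epochs(out, h_aa)
  out$data[out$data < 0] <- 0  # anti-alias ripple can undershoot zero
  trim_and_downsample(out, trim_ms = trim_ms, target_sfreq = target_sfreq)
}

# Squared magnitude of the analytic signal, per column (FFT method).
analytic_power_mat <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  a <- stats::mvfft(X * w, inverse = TRUE) / n
  Mod(a)^2
}
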