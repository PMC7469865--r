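sine_mat <- function(freq, sfreq, n, amp = 1) {
  matrix(amp * sin(2 * pi * freq * (0:(n - 1)) / sfreq), ncol = 1)
}

test_that("Butterworth band-pass preserves the passband and removes DC", {
  fs <- 250; n <- 2500
  x10 <- sine_mat(10, fs, n)
  y10 <- bandpass_continuous(x10, fs, c(0.1, 40))
  mid <- 500:2000
  expect_equal(max(abs(y10[mid])), 1, tolerance = 0.01)
  ydc <- bandpass_continuous(matrix(rep(100, n), ncol = 1), fs, c(0.1, 40))
  expect_lt(abs(mean(ydc[mid])), 1)
  expect_error(bandpass_continuous(x10, fs, c(0.1, 130)), "Nyquist")
})

test_that("notch attenuates line noise per its own frequency response", {
  fs <- 250; n <- 2500; mid <- 500:2000
  b <- signal::remez(n = 200, f = c(0, 46, 49, 51, 54, 125) / 125,
                     a = c(1, 1, 0, 0, 1, 1))
  # oracle: attenuation predicted from the designed coefficients
  H50 <- abs(erpdecode:::fir_response(b, 50, fs))
  y50 <- notch_continuous(sine_mat(50, fs, n), fs)
  achieved <- max(abs(y50[mid]))
  expect_lt(achieved, 0.05)
  expect_lt(achieved, H50)  # two passes attenuate at least as much as one
  y10 <- notch_continuous(sine_mat(10, fs, n), fs)
  expect_equal(max(abs(y10[mid])), 1, tolerance = 0.02)
})

test_that("least-squares FIR low-pass follows the order rule and its response oracle", {
  fs <- 250
  order <- 3L * floor(fs / 8)
  expect_equal(order, 93L)
  h <- fir_ls_design(order, rbind(c(0, 8, 1), c(10, 125, 0)), fs)
  expect_length(h, 94L)
  expect_equal(h, rev(h))  # linear phase
  H <- abs(erpdecode:::fir_response(h, c(2, 20), fs))
  expect_equal(H[1], 1, tolerance = 0.02)
  expect_lt(H[2], 0.03)  # least-squares ripple just past the transition
  # on epochs: 2 Hz preserved, 20 Hz strongly attenuated (two-pass response)
  n <- 600
  dat <- array(0, dim = c(2, 1, n))
  dat[1, 1, ] <- sine_mat(2, fs, n)
  dat[2, 1, ] <- sine_mat(20, fs, n)
  ep <- toy_epochs(n_trials = 2, channels = "Cz", n_samples = n, t0 = -1000,
                   data = dat)
  out <- lowpass_epochs_8hz(ep)
  mid <- 150:450
  expect_equal(max(abs(out$data[1, 1, mid])), 1, tolerance = 0.02)
  expect_lt(max(abs(out$data[2, 1, mid])), H[2]^2 + 0.005)
  # constant epoch preserved up to the design's passband ripple at DC
  cst <- toy_epochs(n_trials = 1, channels = "Cz", n_samples = n,
                    data = array(5, dim = c(1, 1, n)))
  H0 <- abs(erpdecode:::fir_response(h, 0, fs))
  expect_equal(lowpass_epochs_8hz(cst)$data[1, 1, mid],
               rep(5 * H0^2, length(mid)), tolerance = 1e-3)
  short <- toy_epochs(n_trials = 1, channels = "Cz", n_samples = 100)
  expect_error(lowpass_epochs_8hz(short), "too short")
})

test_that("zero-phase filtering leaves a symmetric pulse's peak in place", {
  fs <- 250; n <- 600
  pulse <- exp(-((0:(n - 1)) - 300)^2 / (2 * 15^2))
  ep <- toy_epochs(n_trials = 1, channels = "Cz", n_samples = n, t0 = -1000,
                   data = array(pulse, dim = c(1, 1, n)))
  out <- lowpass_epochs_8hz(ep)
  expect_equal(which.max(out$data[1, 1, ]), 301, tolerance = 1)
})

test_that("trimming and downsampling yield the canonical 100 and 55 time points", {
  cue <- toy_epochs(n_trials = 2, channels = c("Cz", "Pz"),
                    n_samples = 600, t0 = -1000)
  cue_ds <- trim_and_downsample(cue)
  expect_equal(dim(cue_ds)[3], 100)
  expect_equal(cue_ds$time[1], -800)
  expect_equal(cue_ds$time[100], 1180)
  expect_equal(cue_ds$sfreq, 50)

  tar <- toy_epochs(n_trials = 2, channels = c("Cz", "Pz"),
                    n_samples = 375, t0 = -500, event = "target")
  tar_ds <- trim_and_downsample(tar)
  expect_equal(dim(tar_ds)[3], 55)
  expect_equal(range(tar_ds$time), c(-300, 780))

  # trim 0 at equal rates is the identity
  ident <- trim_and_downsample(cue, trim_ms = 0, target_sfreq = 250)
  expect_equal(ident$data, cue$data)
})

test_that("baseline correction subtracts the window mean exactly", {
  n <- 100
  dat <- array(0, dim = c(1, 1, n))
  dat[1, 1, ] <- c(rep(2, 50), rep(7, 50))
  ep <- toy_epochs(n_trials = 1, channels = "Cz", n_samples = n, t0 = -200,
                   data = dat)
  out <- baseline_correct(ep, c(-200, 0))
  expect_equal(unname(out$data[1, 1, 51]), 5)
  # constant trace maps to zero
  cst <- baseline_correct(toy_epochs(n_trials = 1, channels = "Cz",
                                     n_samples = n, t0 = -200,
                                     data = array(5, dim = c(1, 1, n))))
  expect_equal(max(abs(cst$data)), 0)
  # random trace: window mean is exactly zero afterwards
  rnd <- baseline_correct(toy_epochs(n_trials = 3, channels = c("Cz", "Pz"),
                                     n_samples = n, t0 = -200, seed = 4))
  sel <- rnd$time >= -200 & rnd$time < 0
  expect_equal(max(abs(apply(rnd$data[, , sel], c(1, 2), mean))), 0,
               tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(500, 600)), "no samples")
})

test_that("collapsing target conditions conserves counts and respects symmetry", {
  sides <- data.frame(
    condition = "raw",
    target_side = c(rep("left", 15), rep("right", 15)),
    cue_side = c(rep("left", 10), rep("right", 5), rep("right", 10), rep("left", 5)))
  ep <- toy_epochs(n_trials = 30, n_samples = 10)
  ep$trials <- sides
  out <- collapse_target_conditions(ep)
  expect_equal(sum(out$trials$condition == "cued_target"), 20)
  expect_equal(sum(out$trials$condition == "uncued_target"), 10)
  # swapping both sides leaves the labels invariant
  swapped <- ep
  flip <- function(x) ifelse(x == "left", "right", "left")
  swapped$trials$target_side <- flip(sides$target_side)
  swapped$trials$cue_side <- flip(sides$cue_side)
  expect_equal(collapse_target_conditions(swapped)$trials$condition,
               out$trials$condition)
  expect_error(collapse_target_conditions(toy_epochs()), "target_side")
})

test_that("alpha power features recover a constant envelope for a pure alpha tone", {
  fs <- 250; n <- 600
  dat <- array(0, dim = c(2, 1, n))
  dat[1, 1, ] <- sine_mat(10, fs, n)   # in-band
  dat[2, 1, ] <- sine_mat(2, fs, n)    # out of band
  ep <- toy_epochs(n_trials = 2, channels = "Oz", n_samples = n, t0 = -1000,
                   data = dat)
  feats <- alpha_power_features(ep)
  mid <- feats$time > -500 & feats$time < 900
  # envelope oracle: unit sinusoid -> analytic amplitude 1 -> power 1
  # (up to the accumulated passband ripple of the band-pass and anti-alias
  # stages, each within a few percent)
  expect_equal(mean(feats$data[1, 1, mid]), 1, tolerance = 0.25)
  expect_lt(mean(feats$data[2, 1, mid]), 0.05)
  expect_true(all(feats$data >= 0))
  expect_equal(dim(feats)[3], 100)
})
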