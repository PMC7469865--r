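# Builders for small in-code fixtures used across the test files.

# Minimal epochset filled with given data or Gaussian noise.
toy_epochs <- function(n_trials = 4, channels = c("C3", "C4", "Pz", "Oz"),
                       n_samples = 50, sfreq = 250, t0 = -40,
                       condition = rep(c("cue_left", "cue_right"),
                                       length.out = n_trials),
                       data = NULL, sd = 1, seed = 1, event = "cue") {
  tm <- t0 + (seq_len(n_samples) - 1) * 1000 / sfreq
  if (is.null(data)) {
    set.seed(seed)
    data <- array(rnorm(n_trials * length(channels) * n_samples, sd = sd),
                  dim = c(n_trials, length(channels), n_samples))
  }
  epochset(data, tm, sfreq, channels,
           trials = data.frame(condition = condition,
                               stringsAsFactors = FALSE),
           subject_id = "toy", event = event)
}

# Small but montage-complete simulation config (keeps posterior ROI channels).
small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 2, n_channels = 30,
                   n_trials_per_condition = 12, seed = 101)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Standard light preprocessing used ahead of decoding in the tests.
prep_for_decoding <- function(ep) {
  trim_and_downsample(lowpass_epochs_8hz(baseline_correct(ep)))
}

# Closest pair of points between two segments [a1,a2] and [b1,b2] in R^d;
# used as an independent maximum-margin oracle for 2+2-point training sets
# (the optimal separating hyperplane bisects the closest points of the two
# convex hulls).
closest_segment_points <- function(a1, a2, b1, b2) {
  best <- NULL; bestd <- Inf
  for (s in seq(0, 1, length.out = 141)) {
    pa <- a1 + s * (a2 - a1)
    for (t in seq(0, 1, length.out = 141)) {
      pb <- b1 + t * (b2 - b1)
      d <- sum((pa - pb)^2)
      if (d < bestd) { bestd <- d; best <- list(pa = pa, pb = pb) }
    }
  }
  best
}

max_margin_oracle_predict <- function(train_a, train_b, test) {
  cp <- closest_segment_points(train_a[1, ], train_a[2, ],
                               train_b[1, ], train_b[2, ])
  w <- cp$pa - cp$pb
  mid <- (cp$pa + cp$pb) / 2
  d <- as.vector(test %*% w) - sum(w * mid)
  ifelse(d >= 0, "a", "b")
}
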