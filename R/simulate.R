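#' Configuration for a synthetic cued-attention EEG cohort
#'
#' Defines the study conditions a generated cohort emulates: a cued visual
#' spatial attention experiment with lateralized slow cue-locked components
#' (onset latency depending on the cueing strategy), a target-locked N1 with
#' attention modulation, 1/f plus alpha background noise, and subject-level
#' heterogeneity that couples the planted cue effect to the planted N1
#' modulation and reaction times.
#'
#' The two built-in paradigms mirror the two cueing strategies studied in
#' this line of work: `"instructional"` (unilateral attention focus; early
#' population effect onset, 80 ms; 30 subjects) and `"probabilistic"`
#' (divided attention; later onset, 160 ms; 26 subjects; reaction times are
#' collected for both cued and uncued targets so a validity cost is defined).
#'
#' @param paradigm `"instructional"` or `"probabilistic"`.
#' @param n_subjects cohort size; default 30 (instructional) / 26
#'   (probabilistic).
#' @param n_channels number of EEG channels (10-20 labels; HEOG/VEOG are
#'   appended automatically). Default 30.
#' @param sfreq sampling rate, Hz (default 250).
#' @param cue_epoch_window,target_epoch_window epoch windows in ms,
#'   half-open on the sample grid (defaults -1000..1400 and -500..1000).
#' @param n_trials_per_condition trials per condition (default 240, i.e.
#'   480 trials per subject per locking event).
#' @param effect_onset_ms population mean onset of the lateralized cue
#'   component; default 80/160 by paradigm.
#' @param effect_amplitude_uv population mean amplitude (uV) of the
#'   lateralized cue component. The default (1.0) is a calibration choice:
#'   it puts the simulated group decoding time course in the
#'   qualitatively realistic regime (plateau roughly 0.7-0.9 at the default
#'   trial counts), not a measured quantity.
#' @param n1_coupling dimensionless slope linking the subject's late
#'   cue-effect amplitude to the planted N1 attention modulation.
#' @param rt_coupling ms of reaction-time change per uV of planted target
#'   effect (larger attention effect, faster valid responses / larger
#'   validity cost).
#' @param noise_alpha_power variance (uV^2) of the 8-13 Hz background
#'   oscillation, posterior-weighted.
#' @param noise_pink_exponent spectral exponent of the 1/f^a background.
#' @param noise_pink_sd standard deviation (uV) of the 1/f background per
#'   channel before spatial mixing.
#' @param eog_leak amplitude (uV) of an optional condition-locked frontal
#'   eye-movement artifact added to the cue epochs (0 = clean data).
#' @param seed master seed; all subject-level randomness is derived from it
#'   deterministically, so identical configs give bit-identical cohorts.
#' @param amplitude_sdlog,onset_sd_ms,ramp_ms between-subject log-normal
#'   spread of the cue effect, normal spread of its onset (ms), and rise
#'   time of the ramp (ms).
#' @param link_window,link_strength,link_sdlog the late cue-target window
#'   (ms) carrying the between-subject coupling bump, its mean amplitude as
#'   a fraction of `effect_amplitude_uv`, and its log-normal spread.
#' @param n1_base_uv,n1_mod_base_uv,n1_noise_sd N1 amplitude common to both
#'   conditions (uV, negative), baseline attention modulation magnitude
#'   (uV), and subject-level noise of the planted modulation (uV).
#' @param rt_baseline_ms,rt_sd_ms,rt_diff_base_ms mean RT of an average
#'   subject, trial-level RT noise, and baseline validity cost
#'   (probabilistic paradigm).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(paradigm = c("instructional", "probabilistic"),
                       n_subjects = NULL,
                       n_channels = 30,
                       sfreq = 250,
                       cue_epoch_window = c(-1000, 1400),
                       target_epoch_window = c(-500, 1000),
                       n_trials_per_condition = 240,
                       effect_onset_ms = NULL,
                       effect_amplitude_uv = 1.0,
                       n1_coupling = 0.8,
                       rt_coupling = 40,
                       noise_alpha_power = 10,
                       noise_pink_exponent = 1,
                       noise_pink_sd = 6,
                       eog_leak = 0,
                       seed = 1,
                       amplitude_sdlog = 0.4,
                       onset_sd_ms = 10,
                       ramp_ms = 200,
                       link_window = c(460, 660),
                       link_strength = 0.6,
                       link_sdlog = 0.5,
                       n1_base_uv = -2.5,
                       n1_mod_base_uv = 0.4,
                       n1_noise_sd = 0.25,
                       rt_baseline_ms = NULL,
                       rt_sd_ms = 90,
                       rt_diff_base_ms = 50) {
  paradigm <- match.arg(paradigm)
  if (is.null(n_subjects)) n_subjects <- if (paradigm == "instructional") 30 else 26
  if (is.null(effect_onset_ms)) effect_onset_ms <- if (paradigm == "instructional") 80 else 160
  if (is.null(rt_baseline_ms)) rt_baseline_ms <- if (paradigm == "instructional") 470 else 502
  cfg <- list(paradigm = paradigm, n_subjects = as.integer(n_subjects),
              n_channels = as.integer(n_channels), sfreq = sfreq,
              cue_epoch_window = cue_epoch_window,
              target_epoch_window = target_epoch_window,
              n_trials_per_condition = as.integer(n_trials_per_condition),
              effect_onset_ms = effect_onset_ms,
              effect_amplitude_uv = effect_amplitude_uv,
              n1_coupling = n1_coupling, rt_coupling = rt_coupling,
              noise_alpha_power = noise_alpha_power,
              noise_pink_exponent = noise_pink_exponent,
              noise_pink_sd = noise_pink_sd, eog_leak = eog_leak,
              seed = as.integer(seed),
              amplitude_sdlog = amplitude_sdlog, onset_sd_ms = onset_sd_ms,
              ramp_ms = ramp_ms, link_window = link_window,
              link_strength = link_strength, link_sdlog = link_sdlog,
              n1_base_uv = n1_base_uv, n1_mod_base_uv = n1_mod_base_uv,
              n1_noise_sd = n1_noise_sd, rt_baseline_ms = rt_baseline_ms,
              rt_sd_ms = rt_sd_ms, rt_diff_base_ms = rt_diff_base_ms)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$sfreq > 0, cfg$n_subjects >= 1, cfg$n_channels >= 2,
            cfg$n_trials_per_condition >= 1)
  for (w in list(cfg$cue_epoch_window, cfg$target_epoch_window, cfg$link_window)) {
    if (length(w) != 2 || w[1] >= w[2]) stop("window bounds must satisfy start < end")
  }
  if (any(c(cfg$noise_pink_sd, cfg$noise_alpha_power, cfg$eog_leak) < 0))
    stop("noise amplitudes must be nonnegative")
  invisible(cfg)
}

# Sample time axis for a half-open window [start, end) at sfreq.
time_axis <- function(window, sfreq) {
  step <- 1000 / sfreq
  seq(window[1], window[2] - step / 2, by = step)
}

#' Draw the per-subject ground-truth parameters of a cohort
#'
#' Subject effect amplitudes are log-normal (positive and right-skewed, which
#' creates the individual differences the between-subject correlations need).
#' The late-window link amplitude is the subject's effect amplitude times an
#' independent log-normal factor, and the planted N1 modulation is linear in
#' the link amplitude with independent Gaussian noise; the N1 modulation is
#' therefore coupled to the subject's effect amplitude, and the implied
#' correlation can be reproduced by direct Monte-Carlo simulation of the
#' same three-stage model (a recovery oracle for the generator).
#'
#' @param config a [sim_config()].
#' @return data.frame, one row per subject: planted effect amplitude (uV),
#'   effect onset (ms), late-window link amplitude (uV), N1 modulation (uV,
#'   negative sign maintained), planted mean RT and validity cost (ms), and
#'   the coupling coefficients used.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  out <- lapply(seq_len(config$n_subjects) - 1L, function(i) {
    draw_subject_truth(config, i)
  })
  do.call(rbind, out)
}

draw_subject_truth <- function(config, subject_index) {
  seed_i <- derive_seed(config$seed, subject_index)
  with_seed(derive_seed(seed_i, 0L), {
    amp <- config$effect_amplitude_uv *
      stats::rlnorm(1, -config$amplitude_sdlog^2 / 2, config$amplitude_sdlog)
    onset <- max(0, config$effect_onset_ms + stats::rnorm(1, 0, config$onset_sd_ms))
    link_amp <- amp * config$link_strength *
      stats::rlnorm(1, -config$link_sdlog^2 / 2, config$link_sdlog)
    n1_mod <- -(config$n1_mod_base_uv + config$n1_coupling * link_amp +
                  stats::rnorm(1, 0, config$n1_noise_sd))
    target_effect <- abs(n1_mod)
    rt_mean <- config$rt_baseline_ms - config$rt_coupling * target_effect
    rt_diff <- if (config$paradigm == "probabilistic")
      config$rt_diff_base_ms + config$rt_coupling * target_effect else NA_real_
    data.frame(subject_id = sprintf("s%02d", subject_index + 1),
               effect_amplitude = amp, effect_onset = onset,
               link_amplitude = link_amp, n1_modulation = n1_mod,
               rt_mean = rt_mean, rt_difference = rt_diff,
               n1_coupling = config$n1_coupling,
               rt_coupling = config$rt_coupling,
               stringsAsFactors = FALSE)
  })
}

# 1/f^a noise + posterior-weighted alpha band noise for a block of epochs,
# spatially mixed by a per-subject orthonormal matrix (realistic channel
# covariance for the activation-pattern transform to act on).
# Returns an array [trials, channels, samples].
make_background <- function(n_trials, n_ch, n_samp, sfreq, pink_sd, pink_exp,
                            alpha_power, alpha_weight, Q) {
  ncol_tot <- n_ch * n_trials
  freqs <- (seq_len(n_samp) - 1) * sfreq / n_samp
  freqs <- pmin(freqs, sfreq - freqs)  # two-sided
  amp_pink <- ifelse(freqs > 0, 1 / pmax(freqs, 1e-6)^(pink_exp / 2), 0)
  amp_alpha <- as.numeric(freqs >= 8 & freqs <= 13)
  spectrum_noise <- function(amp, sd_target) {
    w <- matrix(stats::rnorm(n_samp * ncol_tot), n_samp, ncol_tot)
    f <- stats::mvfft(w) * amp
    x <- Re(stats::mvfft(f, inverse = TRUE)) / n_samp
    s <- stats::sd(as.vector(x))
    if (s > 0) x * (sd_target / s) else x
  }
  pink <- spectrum_noise(amp_pink, pink_sd)
  # mix pink noise across channels: rows = samples*trials, cols = channels
  dim(pink) <- c(n_samp, n_ch, n_trials)
  pk <- matrix(aperm(pink, c(1, 3, 2)), ncol = n_ch)
  pk <- pk %*% t(Q)
  if (alpha_power > 0) {
    alpha <- spectrum_noise(amp_alpha, sqrt(alpha_power))
    dim(alpha) <- c(n_samp, n_ch, n_trials)
    al <- matrix(aperm(alpha, c(1, 3, 2)), ncol = n_ch)
    pk <- pk + sweep(al, 2, alpha_weight, "*")
  }
  dim(pk) <- c(n_samp, n_trials, n_ch)
  aperm(pk, c(2, 3, 1))
}

# Cue-side spatial template: posterior lateralized pair plus a weaker frontal
# pair of opposite polarity ("frontally-posteriorly lateralized"), unit norm.
cue_template <- function(positions) {
  gaussian_template(positions,
                    centers = rbind(c(-0.65, -0.65), c(0.65, -0.65),
                                    c(-0.50, 0.45), c(0.50, 0.45)),
                    widths = 0.35, signs = c(1, -1, -0.6, 0.6))
}

# Posterior-only lateralized template carrying the late coupling bump.
link_template <- function(positions) {
  gaussian_template(positions,
                    centers = rbind(c(-0.65, -0.65), c(0.65, -0.65)),
                    widths = 0.35, signs = c(1, -1))
}

# Posterior template contralateral to a target side (N1 generator).
n1_template <- function(positions, target_side) {
  xc <- if (target_side == "left") 0.65 else -0.65
  gaussian_template(positions, centers = rbind(c(xc, -0.7)), widths = 0.35)
}

# Fronto-central non-lateralized template (late attention difference).
nd_template <- function(positions) {
  gaussian_template(positions, centers = rbind(c(0, 0.25)), widths = 0.45)
}

#' Generate one synthetic subject
#'
#' Produces a cue-locked and a target-locked [epochset()] plus the subject's
#' ground-truth record. Cue epochs contain a lateralized slow component whose
#' polarity mirrors across hemispheres for cue-left vs cue-right, ramping up
#' from the subject's onset, plus a late posterior bump (within
#' `config$link_window`) whose subject-varying amplitude carries the planted
#' brain-behavior coupling. Target epochs contain a contralateral N1
#' (peak ~185 ms) whose amplitude differs between cued and uncued conditions
#' by the planted modulation, plus a later fronto-central attention
#' difference. Background is spatially mixed 1/f noise plus alpha.
#'
#' @param config a [sim_config()].
#' @param subject_index 0-based subject index (`< config$n_subjects`).
#' @return list with elements `cue` (epochset), `target` (epochset) and
#'   `truth` (one-row data.frame).
#' @export
generate_subject <- function(config, subject_index) {
  validate_sim_config(config)
  if (subject_index < 0 || subject_index >= config$n_subjects)
    stop("subject_index out of range")
  truth <- draw_subject_truth(config, subject_index)
  seed_i <- derive_seed(config$seed, subject_index)
  sid <- truth$subject_id

  eeg_labels <- montage_labels(config$n_channels)
  channels <- c(eeg_labels, "HEOG", "VEOG")
  pos <- montage_positions(eeg_labels)
  n_ch <- length(channels)
  alpha_weight <- c(0.6 + 0.8 * exp(-((pos$x)^2 + (pos$y + 0.7)^2) / (2 * 0.45^2)),
                    0.3, 0.3)  # posterior-weighted alpha; small on EOG
  Q <- with_seed(derive_seed(seed_i, 4L), {
    M <- matrix(stats::rnorm(n_ch^2), n_ch)
    qr.Q(qr(M))
  })

  n_cond <- config$n_trials_per_condition
  tmpl_cue <- cue_template(pos)
  tmpl_link <- link_template(pos)

  ## ---- cue-locked epochs ----
  t_cue <- time_axis(config$cue_epoch_window, config$sfreq)
  cue_cond <- with_seed(derive_seed(seed_i, 3L),
                        sample(rep(c("cue_left", "cue_right"), n_cond)))
  n_trials_cue <- length(cue_cond)
  ramp <- pmin(pmax((t_cue - truth$effect_onset) / config$ramp_ms, 0), 1)
  ramp[t_cue < truth$effect_onset] <- 0
  bump_center <- mean(config$link_window)
  bump_sd <- diff(config$link_window) / 2.8
  bump <- exp(-(t_cue - bump_center)^2 / (2 * bump_sd^2))
  # channels x samples signal for cue_left; cue_right mirrors (antisymmetric
  # templates, so the mirror equals the sign flip)
  sig_cue <- truth$effect_amplitude * outer(c(tmpl_cue, 0, 0), ramp) +
    truth$link_amplitude * outer(c(tmpl_link, 0, 0), bump)
  cue_data <- with_seed(derive_seed(seed_i, 1L),
    make_background(n_trials_cue, n_ch, length(t_cue), config$sfreq,
                    config$noise_pink_sd, config$noise_pink_exponent,
                    config$noise_alpha_power, alpha_weight, Q))
  sgn <- ifelse(cue_cond == "cue_left", 1, -1)
  for (tr in seq_len(n_trials_cue))
    cue_data[tr, , ] <- cue_data[tr, , ] + sgn[tr] * sig_cue
  cue <- epochset(cue_data, t_cue, config$sfreq, channels,
                  trials = data.frame(condition = cue_cond,
                                      cue_side = sub("cue_", "", cue_cond),
                                      stringsAsFactors = FALSE),
                  subject_id = sid, event = "cue")
  if (config$eog_leak > 0)
    cue <- inject_eog(cue, config$eog_leak, condition_locked = TRUE)

  ## ---- target-locked epochs ----
  t_tar <- time_axis(config$target_epoch_window, config$sfreq)
  tar_meta <- with_seed(derive_seed(seed_i, 5L), {
    attn <- sample(rep(c("cued", "uncued"), n_cond))
    side <- sample(rep(c("left", "right"), n_cond))
    data.frame(attention = attn, target_side = side,
               cue_side = ifelse(attn == "cued", side,
                                 ifelse(side == "left", "right", "left")),
               stringsAsFactors = FALSE)
  })
  n_trials_tar <- nrow(tar_meta)
  n1_kern <- exp(-(t_tar - 185)^2 / (2 * 25^2))
  nd_kern <- exp(-(t_tar - 350)^2 / (2 * 90^2))
  tmpl_n1 <- list(left = c(n1_template(pos, "left"), 0, 0),
                  right = c(n1_template(pos, "right"), 0, 0))
  tmpl_nd <- c(nd_template(pos), 0, 0)
  nd_amp <- 1.2 * abs(truth$n1_modulation)
  tar_data <- with_seed(derive_seed(seed_i, 2L),
    make_background(n_trials_tar, n_ch, length(t_tar), config$sfreq,
                    config$noise_pink_sd, config$noise_pink_exponent,
                    config$noise_alpha_power, alpha_weight, Q))
  for (tr in seq_len(n_trials_tar)) {
    tm <- tmpl_n1[[tar_meta$target_side[tr]]]
    a_n1 <- config$n1_base_uv +
      if (tar_meta$attention[tr] == "cued") truth$n1_modulation else 0
    add <- a_n1 * outer(tm, n1_kern)
    if (tar_meta$attention[tr] == "cued")
      add <- add + nd_amp * outer(tmpl_nd, nd_kern)
    tar_data[tr, , ] <- tar_data[tr, , ] + add
  }
  rt <- with_seed(derive_seed(seed_i, 6L), {
    base <- truth$rt_mean + stats::rnorm(n_trials_tar, 0, config$rt_sd_ms)
    if (config$paradigm == "instructional") {
      base[tar_meta$attention == "uncued"] <- NA_real_  # no response required
    } else {
      base[tar_meta$attention == "uncued"] <-
        base[tar_meta$attention == "uncued"] + truth$rt_difference
    }
    pmax(base, 150)
  })
  correct <- with_seed(derive_seed(seed_i, 7L),
                       stats::runif(n_trials_tar) < 0.985)
  tar_trials <- data.frame(condition = paste0(tar_meta$attention, "_target"),
                           attention = tar_meta$attention,
                           target_side = tar_meta$target_side,
                           cue_side = tar_meta$cue_side,
                           rt = rt, correct = correct,
                           stringsAsFactors = FALSE)
  target <- epochset(tar_data, t_tar, config$sfreq, channels,
                     trials = tar_trials, subject_id = sid, event = "target")
  list(cue = cue, target = target, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; if given, the ground-truth table
#'   (CSV) and the configuration (JSON) are written there.
#' @return list with `subjects` (list of [generate_subject()] results),
#'   `truth` (data.frame, one row per subject) and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  subjects <- lapply(seq_len(config$n_subjects) - 1L,
                     function(i) generate_subject(config, i))
  truth <- do.call(rbind, lapply(subjects, `[[`, "truth"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(truth, file.path(out_dir, "ground_truth.csv"))
    jsonlite::write_json(unclass(config), file.path(out_dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(subjects = subjects, truth = truth, config = config)
}

#' Inject a frontal eye-movement artifact
#'
#' Adds a slow, condition-dependent deflection concentrated on the frontal
#' channels F7/F8 (and HEOG when present), mimicking residual gaze shifts
#' toward the cued side. Used to exercise the F7/F8 channel-subset decoding
#' confound check: with `condition_locked = TRUE` the artifact is decodable
#' from the frontal pair; with `condition_locked = FALSE` the deflection's
#' sign is random per trial and frontal decoding stays at chance.
#'
#' @param epochs an [epochset()] with frontal channels F7 and F8.
#' @param amplitude deflection amplitude in uV (0 returns the input
#'   unchanged).
#' @param condition_locked if TRUE the deflection sign follows the trial
#'   condition; if FALSE it is random per trial.
#' @param seed RNG seed for the random-sign variant.
#' @return a new `epochset`.
#' @export
inject_eog <- function(epochs, amplitude, condition_locked = TRUE, seed = 1) {
  if (amplitude == 0) return(epochs)
  idx <- match(c("F7", "F8"), epochs$channels)
  if (anyNA(idx)) stop("frontal channels F7/F8 not present")
  tt <- epochs$time
  defl <- amplitude / (1 + exp(-(tt - 450) / 90))  # slow gaze drift post-cue
  cond <- epochs$trials$condition
  if (condition_locked) {
    sgn <- ifelse(grepl("left", cond), 1, -1)
  } else {
    sgn <- with_seed(seed, sample(c(-1, 1), length(cond), replace = TRUE))
  }
  out <- epochs
  heog <- match("HEOG", epochs$channels)
  for (tr in seq_along(sgn)) {
    out$data[tr, idx[1], ] <- out$data[tr, idx[1], ] + sgn[tr] * defl
    out$data[tr, idx[2], ] <- out$data[tr, idx[2], ] - sgn[tr] * defl
    if (!is.na(heog))
      out$data[tr, heog, ] <- out$data[tr, heog, ] + sgn[tr] * 2 * defl
  }
  out
}
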