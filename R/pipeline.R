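#' Pipeline configuration
#'
#' Bundles the per-module settings for the canonical end-to-end analyses.
#'
#' @param sim a [sim_config()] describing the cohort (used when the
#'   pipeline generates its own synthetic data).
#' @param decoder a [decoder_config()].
#' @param screen logical: apply the four artifact-rejection criteria before
#'   averaging/decoding (default TRUE).
#' @param criteria a [rejection_criteria()].
#' @param baseline_cue,baseline_target baseline windows, ms.
#' @param q,min_run significance-mask settings.
#' @param n_boot bootstrap resamples for onset distributions.
#' @param n_perm permutation iterations for linkage.
#' @param seed global seed (propagated to decoder/bootstrap substreams).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), decoder = decoder_config(),
                            screen = TRUE, criteria = rejection_criteria(),
                            baseline_cue = c(-200, 0),
                            baseline_target = c(-200, 0),
                            q = 0.05, min_run = 3, n_boot = 100,
                            n_perm = 1000, seed = 1, out_dir = NULL) {
  structure(list(sim = sim, decoder = decoder, screen = screen,
                 criteria = criteria, baseline_cue = baseline_cue,
                 baseline_target = baseline_target, q = q, min_run = min_run,
                 n_boot = n_boot, n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Shared preprocessing for one subject's epochs: optional screening,
# baseline, 8 Hz low-pass, trim + downsample to 50 Hz.
prepare_epochs <- function(epochs, baseline, config) {
  retained <- NULL
  if (config$screen && all(c("HEOG", "VEOG") %in% epochs$channels)) {
    rep_ <- screen_epochs(epochs, config$criteria)
    if (length(rep_$retained) >= 2 * config$decoder$n_groups)
      epochs <- subset_epochs(epochs, trials = rep_$retained)
    retained <- rep_$retained
  }
  epochs <- baseline_correct(epochs, baseline)
  epochs <- lowpass_epochs_8hz(epochs)
  epochs <- trim_and_downsample(epochs)
  attr(epochs, "retained") <- retained
  epochs
}

#' Cue-locked decoding pipeline
#'
#' For each subject: artifact screening, baseline correction, 8 Hz low-pass,
#' trimming/downsampling, and the trial-averaged SVM decoding time course
#' (cue left vs cue right); then group-level signed-rank significance
#' masking, onset extraction and the bootstrap onset distribution.
#'
#' @param cohort a cohort list from [generate_cohort()] (or a list of
#'   subject lists with a `cue` epochset).
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `accuracy` (subjects x time,
#'   smoothed), `accuracy_raw`, `time`, `mask`, `onset`, `onset_boot`,
#'   `timecourses` (per subject), `maps` (channels x time, group mean, when
#'   requested).
#' @export
run_cue_pipeline <- function(cohort, config = pipeline_config()) {
  subjects <- cohort$subjects %||% cohort
  tcs <- lapply(seq_along(subjects), function(i) {
    ep <- prepare_epochs(subjects[[i]]$cue, config$baseline_cue, config)
    dc <- config$decoder
    dc$seed <- derive_seed(config$seed, 1000L + i)
    decode_timecourse(ep, dc)
  })
  finish_pipeline(tcs, config, stage = "cue")
}

#' Target-locked decoding pipeline
#'
#' Identical to [run_cue_pipeline()] but with target-locked epochs: trials
#' are first collapsed across visual fields into cued vs uncued targets.
#'
#' @param cohort a cohort list from [generate_cohort()].
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` (see [run_cue_pipeline()]).
#' @export
run_target_pipeline <- function(cohort, config = pipeline_config()) {
  subjects <- cohort$subjects %||% cohort
  tcs <- lapply(seq_along(subjects), function(i) {
    ep <- collapse_target_conditions(subjects[[i]]$target)
    ep <- prepare_epochs(ep, config$baseline_target, config)
    dc <- config$decoder
    dc$seed <- derive_seed(config$seed, 2000L + i)
    decode_timecourse(ep, dc)
  })
  finish_pipeline(tcs, config, stage = "target")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finish_pipeline <- function(tcs, config, stage) {
  time <- tcs[[1]]$time
  acc <- do.call(rbind, lapply(tcs, `[[`, "accuracy_smoothed"))
  acc_raw <- do.call(rbind, lapply(tcs, `[[`, "accuracy"))
  rownames(acc) <- rownames(acc_raw) <- vapply(tcs, `[[`, "", "subject_id")
  mask <- onset <- onset_boot <- NULL
  if (nrow(acc) >= 6) {
    p <- signed_rank_timecourse(acc)
    mask <- fdr_contiguity_mask(p, q = config$q, min_run = config$min_run)
    onset <- extract_onset(mask, time)
    onset_boot <- tryCatch(
      bootstrap_onsets(acc, time, n_boot = config$n_boot, q = config$q,
                       min_run = config$min_run,
                       seed = derive_seed(config$seed, 3000L)),
      error = function(e) NULL)
  }
  maps <- NULL
  if (!is.null(tcs[[1]]$maps)) {
    maps <- Reduce(`+`, lapply(tcs, `[[`, "maps")) / length(tcs)
  }
  out <- structure(list(accuracy = acc, accuracy_raw = acc_raw, time = time,
                        mask = mask, onset = onset, onset_boot = onset_boot,
                        timecourses = tcs, maps = maps, stage = stage,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(out, config$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s-locked: %d subjects x %d time points\n",
              x$stage, nrow(x$accuracy), ncol(x$accuracy)))
  cat(sprintf("  grand-mean accuracy %.3f; onset %s ms\n",
              mean(x$accuracy),
              if (is.null(x$onset) || is.na(x$onset)) "none" else x$onset))
  invisible(x)
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(out_dir, res$stage)
  acc_df <- data.frame(subject_id = rownames(res$accuracy),
                       res$accuracy, check.names = FALSE)
  data.table::fwrite(acc_df, paste0(pre, "_accuracy.csv"))
  if (!is.null(res$mask)) {
    data.table::fwrite(data.frame(time_ms = res$time, p = res$mask$p,
                                  q_adjusted = res$mask$q_adjusted,
                                  significant = res$mask$mask),
                       paste0(pre, "_mask.csv"))
  }
  if (!is.null(res$onset_boot)) {
    data.table::fwrite(data.frame(resample = seq_along(res$onset_boot$onsets),
                                  onset_ms = res$onset_boot$onsets),
                       paste0(pre, "_bootstrap_onsets.csv"))
  }
  if (!is.null(res$maps)) {
    data.table::fwrite(data.frame(channel = rownames(res$maps), res$maps,
                                  check.names = FALSE),
                       paste0(pre, "_weight_maps.csv"))
  }
  manifest <- list(stage = res$stage,
                   package_version = as.character(utils::packageVersion("erpdecode")),
                   seed = res$config$seed,
                   onset_ms = res$onset,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  files <- list.files(out_dir, pattern = paste0("^", res$stage, "_"),
                      full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, paste0(pre, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Brain-behavior linkage pipeline
#'
#' Correlates subjects' decoding accuracies with a per-subject scalar
#' (N1 attention modulation for the cue stage, reaction time or validity
#' cost for the target stage), combining two cohorts meta-analytically when
#' both are supplied, and assesses cluster-level significance with the
#' shared-shuffle permutation test.
#'
#' @param pipeline_results list of `pipeline_result` objects (1 or 2
#'   cohorts; their time axes must match exactly).
#' @param behaviors list of per-subject scalar vectors, same order.
#' @param window ms pair restricting the correlation analysis (0..1200 ms
#'   for the cue stage, 0..560 ms for the target stage).
#' @param config a [pipeline_config()] (permutation settings and seed).
#' @return a `permutation_result` (see [cluster_permutation()]).
#' @export
run_linkage <- function(pipeline_results, behaviors,
                        window = c(0, 1200), config = pipeline_config()) {
  if (inherits(pipeline_results, "pipeline_result"))
    pipeline_results <- list(pipeline_results)
  if (is.numeric(behaviors)) behaviors <- list(behaviors)
  times <- lapply(pipeline_results, `[[`, "time")
  if (length(unique(vapply(times, paste, "", collapse = ","))) != 1)
    stop("cohort time axes must match exactly (no interpolation is performed)")
  sel <- times[[1]] >= window[1] & times[[1]] <= window[2]
  acc <- lapply(pipeline_results, function(r) r$accuracy[, sel, drop = FALSE])
  res <- cluster_permutation(acc, behaviors, times[[1]][sel],
                             n_perm = config$n_perm, alpha = 0.05,
                             seed = derive_seed(config$seed, 4000L))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(res$clusters,
                       file.path(config$out_dir, "linkage_clusters.csv"))
  }
  res
}
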