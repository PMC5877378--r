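#' Pipeline configuration
#'
#' Bundles all stage parameters with cross-stage consistency checks: the
#' epoch window must hold at least one STFT window, the analysis span
#' equals the simulated trial length, and every stage inherits the single
#' sampling rate of the simulation config.
#'
#' @param sim a [sim_config()] describing the cohort to simulate.
#' @param low,high band-pass edges, Hz.
#' @param window_s,overlap epoching window (s) and fractional overlap.
#' @param spectral a [spectral_config()].
#' @param remove_ocular run ICA-based EOG removal; defaults to TRUE exactly
#'   when the simulation injects blinks.
#' @param mrmr_levels discretization levels for MRMR.
#' @param top_n size of the aggregated electrode list.
#' @param out_dir directory for persisted outputs (`NULL` = keep in memory
#'   only).
#' @param persist_raw also write each subject's raw recording to EDF.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            low = 0.1, high = 80,
                            window_s = 2, overlap = 0.5,
                            spectral = spectral_config(),
                            remove_ocular = NULL,
                            mrmr_levels = 3, top_n = 20,
                            out_dir = NULL, persist_raw = FALSE) {
  stopifnot(inherits(sim, "sim_config"), inherits(spectral, "spectral_config"))
  if (window_s * sim$fs < spectral$stft_window) {
    stop("inconsistent configuration: epoch window (", window_s * sim$fs,
         " samples at fs = ", sim$fs, ") is shorter than the STFT window (",
         spectral$stft_window, ")")
  }
  if (window_s > sim$trial_seconds) {
    stop("inconsistent configuration: epoch window exceeds the trial length")
  }
  if (!(high < sim$fs / 2)) {
    stop("inconsistent configuration: band edge ", high,
         " Hz is not below Nyquist for fs = ", sim$fs)
  }
  if (is.null(remove_ocular)) remove_ocular <- sim$blink_rate > 0
  structure(list(sim = sim, low = low, high = high, window_s = window_s,
                 overlap = overlap, spectral = spectral,
                 remove_ocular = remove_ocular, mrmr_levels = mrmr_levels,
                 top_n = top_n, out_dir = out_dir,
                 persist_raw = persist_raw),
            class = "pipeline_config")
}

#' Simulate and featurize one subject
#'
#' Generation, band-pass filtering, optional ocular-artifact removal,
#' baseline stripping, epoching and feature extraction for a single
#' subject, returning the feature matrix (the raw recording is discarded).
#'
#' @param config a [pipeline_config()].
#' @param subject_id subject identifier.
#' @return a `feature_matrix` for the subject (both paradigms).
#' @export
subject_features <- function(config, subject_id) {
  gen <- generate_subject(config$sim, subject_id)
  rec <- bandpass(gen$recording, config$low, config$high)
  if (config$remove_ocular) {
    rec <- remove_eog(rec, seed = config$sim$seed)$recording
  }
  rec <- strip_baseline(rec, pre_trial_s = config$sim$pre_trial_seconds,
                        analysis_seconds = config$sim$trial_seconds)
  ep <- segment_epochs(rec, config$window_s, config$overlap)
  extract_features(ep, config$spectral)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' simulate -> preprocess -> extract features -> MRMR rank -> classify
#' (binary leave-one-clip-out and six-class CV within each paradigm, plus
#' cross-paradigm train-movie/test-recall in both schemes) -> per-class
#' topography summaries. Per-subject feature CSVs, the aggregated ranking
#' CSV and a JSON report are written when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return a report bundle: `features` (per-subject `feature_matrix`
#'   list), `rankings` (per subject x paradigm), `top_electrodes` (per
#'   paradigm), `reports` (classification reports by task/scheme),
#'   `topographies` (DE_gamma per class, recall paradigm), and `log`
#'   (parameters and seeds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  subjects <- seq_len(sim$n_subjects)

  fms <- vector("list", length(subjects))
  for (s in subjects) {
    if (config$persist_raw && !is.null(out)) {
      gen <- generate_subject(sim, s)
      write_recording(gen$recording,
                      file.path(out, sprintf("subject%02d.edf", s)))
    }
    fms[[s]] <- subject_features(config, s)
    if (!is.null(out)) {
      write_features_csv(fms[[s]],
                         file.path(out, sprintf("features_subject%02d.csv", s)))
    }
  }
  names(fms) <- paste0("subject", subjects)

  rankings <- list()
  top_electrodes <- list()
  for (par in c("movie", "recall")) {
    rk <- lapply(subjects, function(s) {
      fm <- filter_epochs(fms[[s]], paradigm = par)
      disc <- discretize_features(fm, n_levels = config$mrmr_levels)
      mrmr_rank(disc, fm$meta$emotion, k = config$top_n)
    })
    rankings[[par]] <- rk
    top_electrodes[[par]] <- aggregate_top_electrodes(rk, config$top_n)
    if (!is.null(out)) {
      utils::write.csv(cbind(rank = seq_len(nrow(top_electrodes[[par]])),
                             top_electrodes[[par]]),
                       file.path(out, sprintf("top_features_%s.csv", par)),
                       row.names = FALSE)
    }
  }

  reports <- list()
  for (par in c("movie", "recall")) {
    reports[[paste0("binary_", par)]] <- summarize_protocol(
      lapply(subjects, function(s)
        binary_leave_one_clip_out(filter_epochs(fms[[s]], paradigm = par))))
    reports[[paste0("six_class_", par)]] <- summarize_protocol(
      lapply(subjects, function(s)
        six_class_cv(filter_epochs(fms[[s]], paradigm = par))))
  }
  for (scheme in c("binary", "six_class")) {
    reports[[paste0("cross_", scheme)]] <- summarize_protocol(
      lapply(subjects, function(s)
        cross_paradigm(filter_epochs(fms[[s]], paradigm = "movie"),
                       filter_epochs(fms[[s]], paradigm = "recall"),
                       scheme = scheme)))
  }

  cohort <- bind_features(fms)
  recall_fm <- filter_epochs(cohort, paradigm = "recall")
  topographies <- lapply(sim$emotions, function(cl)
    class_topography(recall_fm, "DE_gamma", cl))
  names(topographies) <- sim$emotions

  log <- list(seed = sim$seed, n_subjects = sim$n_subjects,
              fs = sim$fs, trial_seconds = sim$trial_seconds,
              band = c(config$low, config$high),
              window_s = config$window_s, overlap = config$overlap,
              stft_window = config$spectral$stft_window,
              effect_size = sim$effect_size,
              recall_attenuation = sim$recall_attenuation,
              effect_channels = sim$effect_channels,
              blink_rate = sim$blink_rate,
              remove_ocular = config$remove_ocular,
              mrmr_levels = config$mrmr_levels, top_n = config$top_n)
  bundle <- list(features = fms, rankings = rankings,
                 top_electrodes = top_electrodes, reports = reports,
                 topographies = topographies, log = log)
  if (!is.null(out)) {
    summary <- lapply(reports, function(r)
      list(task = r$task, scheme = r$scheme,
           subject_accuracy = r$subject_accuracy,
           mean_accuracy = r$mean_accuracy, sd_accuracy = r$sd_accuracy,
           confusion = r$confusion,
           auc = if (!is.null(r$roc)) r$roc$auc else NULL))
    jsonlite::write_json(list(log = log, reports = summary),
                         file.path(out, "report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(bundle)
}
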