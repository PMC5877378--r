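#' Ground-truth recovery experiment on synthetic cohorts
#'
#' Runs the validation study the package uses to demonstrate that the whole
#' pipeline recovers a known class signal: cohorts with the full
#' six-emotion, dual-paradigm trial structure (61 channels, 512 Hz) and a
#' gamma-band class effect at the default effect channels
#' (T7, T8, TP8, AF7, O1). Four measurements are made:
#'
#' 1. *Electrode recovery*: per-subject six-class MRMR rankings on the
#'    recall paradigm are aggregated; the effect channels' gamma-DE
#'    features should populate the aggregated top 20.
#' 2. *Binary decodability*: within-movie leave-one-clip-out accuracy on
#'    the effect cohort, against a null cohort with `effect_size = 0`.
#'    The classifier's own chance level is estimated by Monte-Carlo: the
#'    same protocol re-run on the null cohort with the clip-to-class
#'    assignment permuted gives a chance distribution the null accuracy
#'    must be consistent with; a one-sided binomial bound above the
#'    majority-class rate guards against information leakage.
#' 3. *Cross-paradigm attenuation*: train-movie/test-recall binary
#'    accuracy across recall attenuations 1.0 / 0.7 / 0.3 on seed-paired
#'    cohorts (identical noise realizations), which should decrease
#'    monotonically.
#' 4. *Feature-count comparison*: per-subject binary accuracy using each
#'    subject's top-10 MRMR features versus all 366 features.
#'
#' Trials are `trial_seconds` long (default 10 s; the protocol's full 50 s
#' trials are supported but proportionally slower).
#'
#' @param seed master integer seed.
#' @param n_subjects cohort size for recovery, decodability and the
#'   feature-count comparison.
#' @param n_attenuation_subjects cohort size for the attenuation sweep.
#' @param trial_seconds trial length used for the synthetic cohorts.
#' @param rest_seconds resting-baseline length.
#' @param top_n aggregated electrode-list size.
#' @param attenuations recall attenuation levels for the sweep (decreasing).
#' @param n_permutations label permutations per null subject for the
#'   Monte-Carlo chance distribution.
#' @return list with `top_features` (aggregated data.frame),
#'   `recovered_channels`, `effect_channels`, `binary_effect` /
#'   `binary_null` (classification reports), `chance_rate` (majority
#'   rate, %), `chance_accuracies` (label-permutation accuracies, %),
#'   `chance_ci` (95% interval for the null cohort mean under the
#'   permutation chance distribution, %), `leakage_upper` (one-sided 95%
#'   binomial bound above the majority rate for the pooled null test
#'   count, %), `cross_by_attenuation` (named mean accuracies, %), and
#'   `top10_accuracy` / `all366_accuracy` (mean %, and per subject).
#' @export
recovery_experiment <- function(seed = 1, n_subjects = 5,
                                n_attenuation_subjects = 3,
                                trial_seconds = 10, rest_seconds = 60,
                                top_n = 20,
                                attenuations = c(1.0, 0.7, 0.3),
                                n_permutations = 2) {
  base_cfg <- function(effect_size, attenuation, cohort_seed) {
    pipeline_config(sim = sim_config(
      n_subjects = n_subjects, trial_seconds = trial_seconds,
      rest_seconds = rest_seconds, effect_size = effect_size,
      recall_attenuation = attenuation,
      seed = as.integer(cohort_seed %% 2147483647)))
  }

  cfg_eff <- base_cfg(1, 0.7, seed)
  cfg_null <- base_cfg(0, 0.7, seed + 1000)

  rankings <- vector("list", n_subjects)
  binary_eff <- vector("list", n_subjects)
  binary_null <- vector("list", n_subjects)
  top10_acc <- numeric(n_subjects)
  all366_acc <- numeric(n_subjects)
  cross_eff <- vector("list", n_subjects)
  chance_acc <- numeric(0)

  for (s in seq_len(n_subjects)) {
    fm <- subject_features(cfg_eff, s)
    movie <- filter_epochs(fm, paradigm = "movie")
    recall <- filter_epochs(fm, paradigm = "recall")

    rankings[[s]] <- mrmr_rank(discretize_features(recall),
                               recall$meta$emotion, k = top_n)
    binary_eff[[s]] <- binary_leave_one_clip_out(movie)
    all366_acc[s] <- binary_eff[[s]]$accuracy * 100
    cross_eff[[s]] <- cross_paradigm(movie, recall, scheme = "binary")

    rk_movie <- mrmr_rank(discretize_features(movie), movie$meta$emotion,
                          k = 10)
    top10 <- movie
    top10$X <- movie$X[, rk_movie$order, drop = FALSE]
    top10_acc[s] <- binary_leave_one_clip_out(top10)$accuracy * 100

    fm_null <- filter_epochs(subject_features(cfg_null, s),
                             paradigm = "movie")
    binary_null[[s]] <- binary_leave_one_clip_out(fm_null)

    # Monte-Carlo chance: same protocol, clip-to-class assignment permuted
    set.seed(as.integer((seed + 7 * s) %% 2147483647))
    eligible <- sort(unique(fm_null$meta$clip_id[
      fm_null$meta$emotion != "neutral"]))
    clip_emo <- fm_null$meta$emotion[match(eligible, fm_null$meta$clip_id)]
    for (p in seq_len(n_permutations)) {
      relabel <- setNames(sample(clip_emo), eligible)  # permute clip labels
      perm <- fm_null
      hit <- perm$meta$clip_id %in% eligible
      perm$meta$emotion[hit] <-
        unname(relabel[as.character(perm$meta$clip_id[hit])])
      chance_acc <- c(chance_acc,
                      binary_leave_one_clip_out(perm)$accuracy * 100)
    }
  }

  top_features <- aggregate_top_electrodes(rankings, top_n = top_n)
  eff_ch <- cfg_eff$sim$effect_channels
  gamma_feats <- paste0(eff_ch, "_DE_gamma")
  recovered <- eff_ch[gamma_feats %in% top_features$feature]

  rep_eff <- summarize_protocol(binary_eff)
  rep_null <- summarize_protocol(binary_null)
  chance <- 12 / 15
  n_test <- sum(rep_null$confusion)
  leakage_upper <- 100 * (chance + 1.645 * sqrt(chance * (1 - chance) / n_test))
  # 95% interval for the null-cohort mean under the permutation chance
  # distribution (two independent small samples of the same distribution)
  se <- stats::sd(chance_acc) * sqrt(1 / n_subjects + 1 / length(chance_acc))
  chance_ci <- c(lower = mean(chance_acc) - 1.96 * se,
                 upper = mean(chance_acc) + 1.96 * se)

  # attenuation sweep on seed-paired cohorts (same noise, movie side fixed)
  cross_acc <- numeric(length(attenuations))
  names(cross_acc) <- sprintf("attenuation_%g", attenuations)
  for (a in seq_along(attenuations)) {
    att <- attenuations[a]
    if (att == 0.7) {
      accs <- vapply(cross_eff[seq_len(n_attenuation_subjects)],
                     `[[`, numeric(1), "accuracy")
    } else {
      cfg_a <- base_cfg(1, att, seed)
      accs <- vapply(seq_len(n_attenuation_subjects), function(s) {
        fm <- subject_features(cfg_a, s)
        cross_paradigm(filter_epochs(fm, paradigm = "movie"),
                       filter_epochs(fm, paradigm = "recall"),
                       scheme = "binary")$accuracy
      }, numeric(1))
    }
    cross_acc[a] <- mean(accs) * 100
  }

  list(top_features = top_features,
       effect_channels = eff_ch,
       recovered_channels = recovered,
       binary_effect = rep_eff,
       binary_null = rep_null,
       chance_rate = chance * 100,
       chance_accuracies = chance_acc,
       chance_ci = chance_ci,
       leakage_upper = leakage_upper,
       cross_by_attenuation = cross_acc,
       top10_accuracy = mean(top10_acc),
       all366_accuracy = mean(all366_acc),
       top10_accuracy_by_subject = top10_acc,
       all366_accuracy_by_subject = all366_acc)
}
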