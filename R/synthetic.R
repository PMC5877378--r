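#' Simulation configuration for the six-emotion movie/recall protocol
#'
#' Defines the study conditions emulated by the generator: per subject,
#' 18 movie-viewing trials and 18 recall (self-elicitation) trials of
#' `trial_seconds` each — 3 clips for each of six emotions — preceded by a
#' resting baseline and 5 s pre-trial baselines, sampled at `fs` Hz over a
#' 61-channel 10-20 montage. The class signal is a band-limited gamma
#' oscillation at `effect_channels` whose amplitude depends on the emotion;
#' recall trials carry the same effect attenuated by `recall_attenuation`.
#' The background is 1/f^`noise_exponent` pink noise.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_clips_per_emotion clips per emotion category (default 3).
#' @param emotions ordered set of 6 unique emotion labels.
#' @param trial_seconds duration of each analysed trial block in seconds.
#' @param fs sampling rate, Hz; `trial_seconds * fs` must be an integer.
#' @param channels optional channel-name subset (default: full 61-channel
#'   montage); must contain every `effect_channels` entry.
#' @param effect_channels channels carrying the class-dependent oscillation.
#' @param effect_band name of the band carrying the effect (see [eeg_bands()]).
#' @param effect_freq `c(low, high)` Hz of the oscillation, inside the band.
#' @param effect_size non-negative scalar scaling all class multipliers;
#'   0 removes the class signal entirely (amplitudes become class-independent).
#' @param class_multipliers 6 x length(effect_channels) matrix of per-class
#'   relative amplitude gains (rows in `emotions` order); `NULL` for the
#'   built-in defaults (joy strongest temporally/occipitally, disgust
#'   strongest prefrontally, neutral zero, asymmetric negative emotions).
#' @param recall_attenuation factor in `[0, 1]` applied to the class effect
#'   in recall trials (default 0.7: shared but weaker patterns).
#' @param noise_sd standard deviation of the pink-noise background, µV.
#' @param noise_exponent spectral slope of the background (power ∝ 1/f^exp).
#' @param osc_amplitude baseline RMS amplitude of the oscillation, µV.
#' @param blink_rate blink events per minute added after generation
#'   (0 = clean recordings; see [inject_blinks()]).
#' @param pre_trial_seconds pre-trial baseline span before every trial.
#' @param rest_seconds initial resting baseline span.
#' @param seed master integer seed; subject-level seeds are derived from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 1,
                       n_clips_per_emotion = 3,
                       emotions = emotion_levels(),
                       trial_seconds = 50,
                       fs = 512,
                       channels = NULL,
                       effect_channels = c("T7", "T8", "TP8", "AF7", "O1"),
                       effect_band = "gamma",
                       effect_freq = c(36, 44),
                       effect_size = 1,
                       class_multipliers = NULL,
                       recall_attenuation = 0.7,
                       noise_sd = 10,
                       noise_exponent = 1,
                       osc_amplitude = 2,
                       blink_rate = 0,
                       pre_trial_seconds = 5,
                       rest_seconds = 240,
                       seed = 1) {
  err <- function(field, msg) stop("invalid `", field, "`: ", msg, call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) err("fs", "must be positive")
  if (abs(trial_seconds * fs - round(trial_seconds * fs)) > 1e-9) {
    err("trial_seconds", "trial_seconds * fs must be an integer sample count")
  }
  if (!is.numeric(effect_size) || effect_size < 0) {
    err("effect_size", "must be >= 0")
  }
  if (length(emotions) != 6 || anyDuplicated(emotions)) {
    err("emotions", "must be 6 unique labels")
  }
  if (blink_rate < 0) err("blink_rate", "must be >= 0")
  if (recall_attenuation < 0 || recall_attenuation > 1) {
    err("recall_attenuation", "must be in [0, 1]")
  }
  layout <- channel_layout(channels)
  if (!all(effect_channels %in% layout$name)) {
    err("effect_channels", paste("not in layout:",
        paste(setdiff(effect_channels, layout$name), collapse = ", ")))
  }
  bands <- eeg_bands()
  if (!effect_band %in% names(bands)) err("effect_band", "unknown band name")
  b <- bands[[effect_band]]
  if (effect_freq[1] < b[1] || effect_freq[2] > b[2] ||
      effect_freq[1] >= effect_freq[2]) {
    err("effect_freq", sprintf("must lie inside the %s band (%g-%g Hz)",
                               effect_band, b[1], b[2]))
  }
  if (is.null(class_multipliers)) {
    class_multipliers <- default_class_multipliers(layout, effect_channels)
  }
  if (!is.matrix(class_multipliers) ||
      nrow(class_multipliers) != 6 ||
      ncol(class_multipliers) != length(effect_channels)) {
    err("class_multipliers",
        "must be a 6 x length(effect_channels) matrix")
  }
  rownames(class_multipliers) <- emotions
  colnames(class_multipliers) <- effect_channels
  structure(list(n_subjects = n_subjects,
                 n_clips_per_emotion = n_clips_per_emotion,
                 emotions = emotions, trial_seconds = trial_seconds, fs = fs,
                 layout = layout, effect_channels = effect_channels,
                 effect_band = effect_band, effect_freq = effect_freq,
                 effect_size = effect_size,
                 class_multipliers = class_multipliers,
                 recall_attenuation = recall_attenuation,
                 noise_sd = noise_sd, noise_exponent = noise_exponent,
                 osc_amplitude = osc_amplitude, blink_rate = blink_rate,
                 pre_trial_seconds = pre_trial_seconds,
                 rest_seconds = rest_seconds, seed = as.integer(seed)),
            class = "sim_config")
}

# Region-based default gains: temporal and occipital sites load on joy,
# prefrontal on disgust, neutral carries no class signal, and the negative
# emotions are laterally asymmetric over the temporal lobe.
default_class_multipliers <- function(layout, effect_channels) {
  region <- function(ch) {
    r <- layout[layout$name == ch, ]
    if (r$y > 0.5) "prefrontal"
    else if (r$y < -0.6) "occipital"
    else if (abs(r$x) > 0.6) if (r$x < 0) "temporal_l" else "temporal_r"
    else "central"
  }
  profile <- rbind(
    joy     = c(prefrontal = 0.30, temporal_l = 1.00, temporal_r = 1.00,
                occipital = 0.90, central = 0.60),
    neutral = c(prefrontal = 0.00, temporal_l = 0.00, temporal_r = 0.00,
                occipital = 0.00, central = 0.00),
    sad     = c(prefrontal = 0.25, temporal_l = 0.45, temporal_r = 0.25,
                occipital = 0.20, central = 0.20),
    disgust = c(prefrontal = 1.00, temporal_l = 0.50, temporal_r = 0.50,
                occipital = 0.30, central = 0.40),
    anger   = c(prefrontal = 0.55, temporal_l = 0.50, temporal_r = 0.70,
                occipital = 0.35, central = 0.45),
    fear    = c(prefrontal = 0.45, temporal_l = 0.45, temporal_r = 0.65,
                occipital = 0.50, central = 0.50))
  m <- sapply(effect_channels, function(ch) profile[, region(ch)])
  matrix(m, nrow = 6, dimnames = list(rownames(profile), effect_channels))
}

# 1/f^a spectrally shaped Gaussian noise. The FFT length is padded to the
# next 5-smooth integer (and truncated after shaping) so the transform stays
# fast for arbitrary recording lengths.
pink_noise <- function(n, fs, exponent, sd) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w * sd)
  n2 <- stats::nextn(n, c(2, 3, 5))
  if (n2 > n) w <- c(w, numeric(n2 - n))
  f <- seq(0, fs / 2, length.out = floor(n2 / 2) + 1)
  shape <- c(0, pmax(f[-1], 0.1)^(-exponent / 2))
  spec <- stats::fft(w)
  full <- if (n2 %% 2 == 0) c(shape, rev(shape[2:(length(shape) - 1)])) else
    c(shape, rev(shape[-1]))
  x <- Re(stats::fft(spec * full, inverse = TRUE))[seq_len(n)] / n2
  x * sd / stats::sd(x)
}

# Band-limited unit-RMS noise carrier via FFT masking.
narrowband_noise <- function(n, fs, low, high) {
  w <- stats::rnorm(n)
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  keep <- as.numeric(f >= low & f <= high)
  full <- if (n %% 2 == 0) c(keep, rev(keep[2:(length(keep) - 1)])) else
    c(keep, rev(keep[-1]))
  x <- Re(stats::fft(stats::fft(w) * full, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

subject_seed <- function(master_seed, subject_id) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(subject_id) * 104729) %% 2147483647)
}

#' Generate one subject's synthetic EEG recording
#'
#' Produces a full-session recording with the protocol's trial structure:
#' `rest_seconds` of resting baseline, then for each of the 18 clips a 5 s
#' pre-trial baseline + movie trial followed by a 5 s pre-trial baseline +
#' recall trial. Every channel carries 1/f background noise; the
#' `effect_channels` additionally carry a band-limited oscillation whose
#' amplitude is `osc_amplitude * (1 + effect_size * multiplier[class] *
#' attenuation)`, with attenuation 1 for movie trials and
#' `recall_attenuation` for recall trials. Amplitude parameters consume no
#' random draws, so cohorts differing only in `effect_size` or attenuation
#' share identical noise realizations under the same seed.
#'
#' @param config a [sim_config()].
#' @param subject_id integer subject identifier (seeds are derived from the
#'   master seed and this id).
#' @return list with elements `recording` (a [raw_recording()]) and `truth`
#'   (ground truth: informative (channel, band) pairs, the class multiplier
#'   matrix, and blink event times, empty unless blinks are injected).
#' @export
generate_subject <- function(config, subject_id = 1) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  lay <- config$layout
  n_ch <- nrow(lay)
  n_clips <- 6 * config$n_clips_per_emotion
  tr_n <- round(config$trial_seconds * fs)
  pre_n <- round(config$pre_trial_seconds * fs)
  rest_n <- round(config$rest_seconds * fs)
  n_total <- rest_n + n_clips * 2 * (pre_n + tr_n)

  set.seed(subject_seed(config$seed, subject_id))
  data <- matrix(0, n_ch, n_total)
  for (ch in seq_len(n_ch)) {
    data[ch, ] <- pink_noise(n_total, fs, config$noise_exponent,
                             config$noise_sd)
  }

  # clip c belongs to emotion ceiling(c / clips_per_emotion)
  clip_emotion <- rep(config$emotions, each = config$n_clips_per_emotion)
  eff_idx <- match(config$effect_channels, lay$name)
  ann <- vector("list", n_clips * 2)
  pos <- rest_n
  k <- 0
  for (clip in seq_len(n_clips)) {
    emo <- clip_emotion[clip]
    for (paradigm in c("movie", "recall")) {
      pos <- pos + pre_n                      # pre-trial baseline span
      atten <- if (paradigm == "movie") 1 else config$recall_attenuation
      for (j in seq_along(eff_idx)) {
        carrier <- narrowband_noise(tr_n, fs, config$effect_freq[1],
                                    config$effect_freq[2])
        amp <- config$osc_amplitude *
          (1 + config$effect_size * atten *
             config$class_multipliers[emo, j])
        idx <- (pos + 1):(pos + tr_n)
        data[eff_idx[j], idx] <- data[eff_idx[j], idx] + amp * carrier
      }
      k <- k + 1
      ann[[k]] <- data.frame(trial_index = k, paradigm = paradigm,
                             clip_id = clip, emotion = emo,
                             onset_s = pos / fs,
                             duration_s = config$trial_seconds,
                             stringsAsFactors = FALSE)
      pos <- pos + tr_n
    }
  }
  ann <- do.call(rbind, ann)
  rec <- raw_recording(data, fs, lay, ann, subject_id = subject_id)
  truth <- list(
    informative = data.frame(channel = config$effect_channels,
                             band = config$effect_band,
                             stringsAsFactors = FALSE),
    class_multipliers = config$class_multipliers,
    blink_times = numeric(0))
  if (config$blink_rate > 0) {
    rec <- inject_blinks(rec, config$blink_rate,
                         seed = subject_seed(config$seed, subject_id) + 1L)
    truth$blink_times <- rec$blinks
  }
  list(recording = rec, truth = truth)
}

#' Inject stereotyped eye-blink artifacts into a recording
#'
#' Adds blink transients at Poisson-distributed times: a 0.4 s squared-sine
#' bump (energy concentrated around 0.5-4 Hz) with a frontal-weighted
#' spatial pattern, largest at the FP/AF row and decaying towards posterior
#' sites. Event times (seconds) are returned in the `blinks` element of the
#' recording.
#'
#' @param recording a [raw_recording()].
#' @param rate expected blink events per minute (>= 0; 0 returns the
#'   recording unchanged).
#' @param seed integer seed for event placement.
#' @param amplitude peak blink amplitude at the frontal pole, µV.
#' @param duration_s blink duration in seconds.
#' @return the recording with blinks added and `blinks` (event onset times).
#' @export
inject_blinks <- function(recording, rate, seed = 1, amplitude = 100,
                          duration_s = 0.4) {
  stopifnot(inherits(recording, "raw_recording"), rate >= 0)
  if (rate == 0) {
    recording$blinks <- numeric(0)
    return(recording)
  }
  fs <- recording$fs
  n <- ncol(recording$data)
  total_min <- n / fs / 60
  set.seed(as.integer(seed %% 2147483647))
  n_events <- stats::rpois(1, rate * total_min)
  onsets <- sort(stats::runif(n_events, 0, n / fs - duration_s))
  len <- round(duration_s * fs)
  bump <- amplitude * sin(pi * seq(0, 1, length.out = len))^2
  weights <- exp((recording$layout$y - max(recording$layout$y)) / 0.35)
  for (t0 in onsets) {
    i0 <- round(t0 * fs) + 1L
    idx <- i0:(i0 + len - 1L)
    recording$data[, idx] <- recording$data[, idx] + outer(weights, bump)
  }
  recording$blinks <- onsets
  recording
}
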