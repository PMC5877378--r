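test_that("trial blocks have exactly trial_seconds x fs samples and full label structure", {
  cfg <- sim_config(trial_seconds = 50, rest_seconds = 5,
                    pre_trial_seconds = 5, n_clips_per_emotion = 1,
                    channels = tiny_channels,
                    effect_channels = c("T7", "AF7"), seed = 3)
  g <- generate_subject(cfg, 1)
  ann <- g$recording$annotations
  expect_equal(nrow(ann), 12)                   # 6 clips x 2 paradigms
  expect_true(all(round(ann$duration_s * cfg$fs) == 25600))
  expect_equal(sort(unique(ann$paradigm)), c("movie", "recall"))
  expect_setequal(unique(ann$emotion), emotion_levels())
  # onsets sit on the sample grid and trials do not overlap
  expect_true(all(diff(ann$onset_s) >= ann$duration_s[-nrow(ann)]))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 21)
  g1 <- generate_subject(cfg, 2)
  g2 <- generate_subject(cfg, 2)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$recording$annotations, g2$recording$annotations)
  g3 <- generate_subject(tiny_config(seed = 22), 2)
  expect_false(identical(g1$recording$data, g3$recording$data))
})

test_that("invalid configuration fields raise errors naming the field", {
  expect_error(sim_config(fs = -1), "fs")
  expect_error(sim_config(trial_seconds = 1/3, fs = 100), "trial_seconds")
  expect_error(sim_config(effect_size = -0.1), "effect_size")
  expect_error(sim_config(emotions = c("a", "a", "b", "c", "d", "e")),
               "emotions")
  expect_error(sim_config(effect_channels = "NOPE"), "effect_channels")
  expect_error(sim_config(blink_rate = -2), "blink_rate")
})

test_that("ground truth names the informative channel/band pairs", {
  cfg <- tiny_config()
  g <- generate_subject(cfg, 1)
  expect_setequal(g$truth$informative$channel, cfg$effect_channels)
  expect_true(all(g$truth$informative$band == "gamma"))
  expect_equal(rownames(g$truth$class_multipliers), cfg$emotions)
  # neutral carries no class signal by default
  expect_true(all(g$truth$class_multipliers["neutral", ] == 0))
})

test_that("gamma power at effect channels is monotone in effect_size", {
  gamma_de <- function(effect_size, seed) {
    cfg <- tiny_config(seed = seed, effect_size = effect_size)
    g <- generate_subject(cfg, 1)
    ann <- g$recording$annotations
    joy <- ann[ann$emotion == "joy" & ann$paradigm == "movie", ][1, ]
    i0 <- round(joy$onset_s * cfg$fs)
    ch <- match("T7", g$recording$layout$name)
    x <- g$recording$data[ch, (i0 + 1):(i0 + 1024)]
    band_de(stft_power(x, cfg$fs), c(30, 64))
  }
  for (seed in c(31, 32, 33)) {
    de <- vapply(c(0, 1, 2.5), gamma_de, numeric(1), seed = seed)
    expect_true(all(diff(de) > 0),
                info = sprintf("seed %d: DE %s", seed,
                               paste(round(de, 3), collapse = " ")))
  }
})

test_that("blink injection is additive, frontal-weighted and Poisson-calibrated", {
  cfg <- tiny_config(seed = 41)
  g <- generate_subject(cfg, 1)
  same <- inject_blinks(g$recording, rate = 0)
  expect_identical(same$data, g$recording$data)
  expect_length(same$blinks, 0)

  fp1 <- match("FP1", g$recording$layout$name)
  oz <- match("Oz", g$recording$layout$name)
  counts <- integer(20)
  for (s in 1:20) {
    b <- inject_blinks(g$recording, rate = 12, seed = 100 + s)
    counts[s] <- length(b$blinks)
    if (s == 1) {
      expect_gt(var(b$data[fp1, ]), var(g$recording$data[fp1, ]))
      # frontal dominance of the added component
      added_fp1 <- b$data[fp1, ] - g$recording$data[fp1, ]
      added_oz <- b$data[oz, ] - g$recording$data[oz, ]
      expect_gt(max(abs(added_fp1)), 5 * max(abs(added_oz)))
    }
  }
  dur_min <- ncol(g$recording$data) / cfg$fs / 60
  lambda <- 12 * dur_min
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 20))
})

test_that("with no class effect, the top MI statistic sits in the permutation null", {
  cfg <- tiny_config(seed = 51, effect_size = 0)
  g <- generate_subject(cfg, 1)
  rec <- strip_baseline(bandpass(g$recording),
                        pre_trial_s = cfg$pre_trial_seconds,
                        analysis_seconds = cfg$trial_seconds)
  fm <- extract_features(segment_epochs(rec))
  fm <- filter_epochs(fm, paradigm = "movie")
  disc <- discretize_features(fm)
  top_mi <- max(mi_cols <- vapply(seq_len(ncol(disc$codes)), function(j)
    mutual_information(disc$codes[, j], fm$meta$emotion), numeric(1)))
  set.seed(52)
  null_max <- replicate(30, {
    perm <- sample(fm$meta$emotion)
    max(vapply(seq_len(ncol(disc$codes)), function(j)
      mutual_information(disc$codes[, j], perm), numeric(1)))
  })
  expect_lte(top_mi, quantile(null_max, 0.95) * 1.1)
})
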