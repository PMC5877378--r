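test_that("band-pass removes DC, passes mid-band, and attenuates as designed", {
  fs <- 512
  n <- fs * 40
  t <- (0:(n - 1)) / fs
  lay_ann <- trial_annotations(5, 30)
  mid <- 6000:(n - 6000)

  dc <- make_recording(1, 40, lay_ann, data = matrix(7, 1, n))
  out <- bandpass(dc)
  expect_lt(mean(abs(out$data[1, mid])), 0.01 * 7)

  s10 <- make_recording(1, 40, lay_ann, data = matrix(sin(2 * pi * 10 * t), 1))
  out10 <- bandpass(s10)
  rms_ratio <- sqrt(mean(out10$data[1, mid]^2)) / sqrt(0.5)
  expect_lt(abs(rms_ratio - 1), 0.05)

  s100 <- make_recording(1, 40, lay_ann, data = matrix(sin(2 * pi * 100 * t), 1))
  out100 <- bandpass(s100)
  measured <- sqrt(mean(out100$data[1, mid]^2)) / sqrt(0.5)
  designed <- bandpass_gain(100, fs = fs)
  expect_lt(abs(measured / designed - 1), 0.1)

  expect_error(bandpass(s10, low = 0), "band edges")
  expect_error(bandpass(s10, low = 10, high = 300), "band edges")
})

test_that("ICA reports one source per component and preserves clean data", {
  cfg <- tiny_config(seed = 61, trial_seconds = 6, rest_seconds = 20)
  g <- generate_subject(cfg, 1)
  res <- remove_eog(g$recording, seed = 4)
  expect_equal(nrow(res$report), nrow(g$recording$data))
  # artifact-free recording: nothing flagged, signal essentially untouched
  expect_false(any(res$report$flagged))
  cors <- vapply(seq_len(nrow(g$recording$data)), function(ch)
    cor(g$recording$data[ch, ], res$recording$data[ch, ]), numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("ICA removes injected blinks from frontal channels", {
  cfg <- tiny_config(seed = 62, trial_seconds = 6, rest_seconds = 20)
  g <- generate_subject(cfg, 1)
  rec <- inject_blinks(g$recording, rate = 20, seed = 7)
  # reference blink time course: the injected frontal transient train
  blink <- rec$data - g$recording$data
  fp1 <- match("FP1", rec$layout$name)
  res <- remove_eog(rec, seed = 4)
  expect_true(any(res$report$flagged))
  pre_cor <- abs(cor(rec$data[fp1, ], blink[fp1, ]))
  post_cor <- abs(cor(res$recording$data[fp1, ], blink[fp1, ]))
  expect_gt(pre_cor, 0.7)
  expect_lt(post_cor, 0.3)
  # idempotence in score: a second pass (on the now rank-reduced data)
  # flags nothing new
  res2 <- remove_eog(res$recording,
                     n_components = nrow(rec$data) - sum(res$report$flagged),
                     seed = 4)
  expect_false(any(res2$report$flagged))
})

test_that("ICA rejects rank-deficient input with channel diagnostics", {
  cfg <- tiny_config(seed = 63)
  g <- generate_subject(cfg, 1)
  g$recording$data[2, ] <- g$recording$data[1, ]   # duplicate channel
  expect_error(remove_eog(g$recording), "rank-deficient")
})

test_that("baseline stripping keeps the last analysis span of each trial", {
  fs <- 512
  ann <- trial_annotations(c(10, 80), c(60, 60), paradigm = c("movie", "recall"))
  n <- fs * 145
  marker <- matrix(seq_len(n) / fs, 1)      # encode time in the sample value
  rec <- make_recording(1, 145, ann, data = marker)
  out <- strip_baseline(rec, pre_trial_s = 5, analysis_seconds = 50)
  expect_equal(ncol(out$data), 2 * 50 * fs)
  expect_equal(out$annotations$duration_s, c(50, 50))
  expect_equal(out$annotations$onset_s, c(0, 50))
  # retained span is the LAST 50 s: trial 1 covered 10-70 s, keep 20-70 s
  expect_equal(out$data[1, 1], 20 + 1 / fs, tolerance = 1e-9)
  expect_equal(out$data[1, 50 * fs], 70, tolerance = 1e-9)

  # pre_trial_s = 0 keeps trials unchanged
  ann2 <- trial_annotations(0, 50)
  rec2 <- make_recording(1, 50, ann2)
  out2 <- strip_baseline(rec2, pre_trial_s = 0, analysis_seconds = 50)
  expect_identical(out2$data, rec2$data)

  # trial shorter than the analysis span errors, naming the trial
  ann3 <- trial_annotations(10, 30)
  rec3 <- make_recording(1, 45, ann3)
  expect_error(strip_baseline(rec3, analysis_seconds = 50), "trial_index 1")
  # missing pre-trial span errors
  expect_error(strip_baseline(make_recording(1, 55, trial_annotations(2, 50)),
                              pre_trial_s = 5), "pre-trial")
})

test_that("segmentation counts match brute-force sliding-window enumeration", {
  brute <- function(L, W, overlap) {
    hop <- W * (1 - overlap)
    count <- 0; start <- 0
    while (start + W <= L + 1e-9) { count <- count + 1; start <- start + hop }
    count
  }
  fs <- 64
  for (L in c(2, 5, 10, 50)) {
    for (W in c(1, 2)) {
      for (ov in c(0, 0.25, 0.5, 0.75)) {
        if (W > L) next
        rec <- make_recording(1, L + 1, trial_annotations(1, L), fs = fs)
        ep <- segment_epochs(rec, W, ov)
        expect_equal(dim(ep$data)[3], brute(L, W, ov),
                     info = sprintf("L=%g W=%g ov=%g", L, W, ov))
      }
    }
  }
})

test_that("protocol segmentation yields 49 epochs per 50 s trial and 1 at equality", {
  fs <- 512
  rec <- make_recording(1, 51, trial_annotations(0, 50), fs = fs)
  ep <- segment_epochs(rec, 2, 0.5)
  expect_equal(dim(ep$data)[3], 49)
  expect_equal(dim(segment_epochs(rec, 2, 0)$data)[3], 25)
  rec1 <- make_recording(1, 3, trial_annotations(0, 2), fs = fs)
  expect_equal(dim(segment_epochs(rec1, 2, 0.5)$data)[3], 1)
  expect_error(segment_epochs(rec1, 4, 0.5), "longer than trial")
  expect_error(segment_epochs(rec1, 2, 1), "overlap")
})

test_that("epochs inherit trial labels and never cross trial boundaries", {
  fs <- 128
  ann <- trial_annotations(c(1, 6), c(4, 4), paradigm = c("movie", "recall"),
                           emotions = c("joy", "joy"), clip_ids = c(1, 1))
  n <- fs * 11
  marker <- matrix(rep(c(0, 1, 0, 2, 0),
                       times = fs * c(1, 4, 1, 4, 1)), 1)
  rec <- make_recording(1, 11, ann, fs = fs, data = marker)
  ep <- segment_epochs(rec, 2, 0.5)
  expect_equal(ep$meta$paradigm, rep(c("movie", "recall"), each = 3))
  # every epoch holds samples from exactly one trial
  for (e in seq_len(dim(ep$data)[3])) {
    expect_length(unique(ep$data[1, , e]), 1)
  }
})

test_that("filtering then segmenting matches per-epoch filtering away from edges", {
  fs <- 512
  set.seed(71)
  rec <- make_recording(1, 14, trial_annotations(1, 12), fs = fs)
  whole <- segment_epochs(bandpass(rec, 4, 40), 2, 0.5)
  eps <- segment_epochs(rec, 2, 0.5)
  flt <- signal::butter(4, c(4, 40) / (fs / 2), "pass")
  # interior epoch, interior samples
  e <- 6
  per_epoch <- eegemotion:::filtfilt_fast(flt$b, flt$a, eps$data[1, , e], 512)
  mid <- 300:700
  expect_gt(cor(whole$data[1, mid, e], per_epoch[mid]), 0.99)
})
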