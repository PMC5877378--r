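test_that("STFT framing, concentration and degenerate inputs behave as designed", {
  fs <- 512
  t <- (0:1023) / fs
  s <- stft_power(sin(2 * pi * 40 * t), fs)
  expect_equal(nrow(s$power), 15)               # (1024 - 128)/64 + 1
  expect_equal(diff(s$freqs)[1], fs / 128)
  # tone power concentrates at the tone: the per-bin share matches an
  # independent single-frame windowed-DFT oracle, and the taper's main
  # lobe (three bins around f) captures >= 90% of the total
  tot <- colSums(s$power)
  near2 <- order(abs(s$freqs - 40))[1:2]
  near3 <- order(abs(s$freqs - 40))[1:3]
  w <- 0.54 - 0.46 * cos(2 * pi * (0:127) / 127)
  oracle <- Mod(fft(w * sin(2 * pi * 40 * (0:127) / fs)))[1:65]^2
  expect_equal(sum(tot[near2]) / sum(tot),
               sum(oracle[near2]) / sum(oracle), tolerance = 1e-6)
  expect_gt(sum(tot[near3]) / sum(tot), 0.9)

  z <- stft_power(numeric(1024), fs)
  expect_true(all(z$power == 0))
  expect_error(stft_power(numeric(64), fs), "shorter than STFT window")
})

test_that("DE obeys the amplitude-scaling identity exactly across bands", {
  fs <- 512
  set.seed(81)
  x <- rnorm(1024)
  a <- 3.7
  for (band in eeg_bands()) {
    d1 <- band_de(stft_power(x, fs), band)
    d2 <- band_de(stft_power(a * x, fs), band)
    expect_equal(d2 - d1, log(a^2), tolerance = 1e-12)
  }
  expect_error(band_de(stft_power(x, fs), c(200, 300)), "spectral range")
})

test_that("DE reflects band power concentration and is stable across noise draws", {
  fs <- 512
  t <- (0:1023) / fs
  alpha_sig <- sin(2 * pi * 10 * t)
  s <- stft_power(alpha_sig, fs)
  expect_gt(band_de(s, c(8, 12)), band_de(s, c(30, 64)))

  # equal-variance white-noise epochs give DE equal within estimator spread
  set.seed(82)
  des <- replicate(40, band_de(stft_power(rnorm(1024), fs), c(30, 64)))
  expect_lt(sd(des), 0.25)
  expect_lt(abs(band_de(stft_power(rnorm(1024), fs), c(30, 64)) - mean(des)),
            4 * sd(des))
})

test_that("zero band power floors at epsilon and is flagged", {
  s <- stft_power(numeric(1024), 512)
  d <- band_de(s, c(30, 64))
  expect_equal(as.numeric(d), log(1e-30))
  expect_true(isTRUE(attr(d, "floored")))
})

test_that("EMD separates a two-tone signal and reconstructs exactly", {
  fs <- 512
  t <- (0:1023) / fs
  slow <- sin(2 * pi * 4 * t)
  fast <- 0.6 * sin(2 * pi * 40 * t + 1)
  e <- emd(slow + fast)
  expect_gte(ncol(e$imfs), 2)
  expect_gt(cor(e$imfs[, 1], fast), 0.95)
  expect_gt(cor(rowSums(e$imfs[, -1, drop = FALSE]) + e$residue, slow), 0.95)
  recon <- rowSums(e$imfs) + e$residue
  expect_lt(max(abs(recon - (slow + fast))), 1e-8 * diff(range(slow + fast)))
})

test_that("EMD respects IMF defining conditions and degenerate inputs", {
  # monotone ramp: no IMFs, residue = input
  r <- emd(seq(0, 1, length.out = 200))
  expect_equal(ncol(r$imfs), 0)
  expect_equal(r$residue, seq(0, 1, length.out = 200))
  expect_error(emd(c(1, NA, 3)), "non-finite")

  # IMF1 of a noisy epoch: extrema and zero crossings differ by at most 1
  # (within the sifting stop tolerance)
  set.seed(83)
  x <- as.numeric(eegemotion:::pink_noise(1024, 512, 1, 1))
  imf1 <- emd(x, max_imf = 1)$imfs[, 1]
  n_zc <- sum(diff(sign(imf1)) != 0)
  d <- diff(imf1)
  n_ext <- sum(d[-length(d)] * d[-1] < 0)
  expect_lte(abs(n_ext - n_zc), 2)
})

test_that("D_t matches hand computation, the sinusoid rate formula, and scaling", {
  expect_equal(as.numeric(dt_feature(c(0, 1, 0, 1))), log(1))
  # dense sinusoid: D_t ~ 4 A f / fs
  fs <- 8192; A <- 2.5; f <- 10
  x <- A * sin(2 * pi * f * (0:(fs - 1)) / fs)
  expect_equal(exp(as.numeric(dt_feature(x))), 4 * A * f / fs,
               tolerance = 1e-3)
  set.seed(84)
  y <- rnorm(500)
  expect_equal(as.numeric(dt_feature(5 * y)) - as.numeric(dt_feature(y)),
               log(5), tolerance = 1e-12)
  cst <- dt_feature(rep(2, 10))
  expect_equal(as.numeric(cst), log(1e-30))
  expect_true(isTRUE(attr(cst, "floored")))
  expect_error(dt_feature(3), "at least 2")
})

test_that("a 61-channel epoch yields 366 named features (305 DE + 61 EMD)", {
  set.seed(85)
  d <- array(rnorm(61 * 1024 * 2), c(61, 1024, 2))
  fm <- extract_features(make_epoch_set(d))
  expect_equal(ncol(fm$X), 366)
  info <- feature_info(colnames(fm$X))
  expect_equal(sum(startsWith(info$family, "DE_")), 305)
  expect_equal(sum(info$family == "EMD_Dt"), 61)
  expect_setequal(unique(info$electrode), channel_layout()$name)
  expect_equal(attr(fm$X, "n_floored"), 0)
})

test_that("feature extraction is deterministic and channel-independent", {
  set.seed(86)
  d <- array(rnorm(10 * 1024 * 3), c(10, 1024, 3))
  lay <- channel_layout(tiny_channels)
  ep <- make_epoch_set(d, layout = lay)
  fm1 <- extract_features(ep)
  fm2 <- extract_features(ep)
  expect_identical(fm1$X, fm2$X)
  expect_equal(ncol(fm1$X), 60)                  # 10 channels x 6 families

  # permuting channels permutes the per-channel feature blocks identically
  perm <- c(3, 1, 2, 5, 4, 7, 6, 10, 9, 8)
  epp <- make_epoch_set(d[perm, , , drop = FALSE],
                        layout = lay[perm, , drop = FALSE])
  fmp <- extract_features(epp)
  expect_equal(fmp$X[, colnames(fm1$X)], fm1$X[, colnames(fm1$X)],
               ignore_attr = TRUE)

  # identical epochs give identical feature vectors
  d2 <- d; d2[, , 2] <- d2[, , 1]
  fme <- extract_features(make_epoch_set(d2, layout = lay))
  expect_identical(fme$X[1, ], fme$X[2, ])
})
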