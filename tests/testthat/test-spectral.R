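test_that("a pure tone peaks at its own frequency in every frame", {
  fs <- 500
  x <- sin(2 * pi * 10 * (0:(fs * 60 - 1)) / fs)
  sp <- multitaper_spectrogram(x, fs, spectral_params(step_s = 1))
  peak_freq <- sp$freqs[apply(sp$power, 1, which.max)]
  expect_true(all(abs(peak_freq - 10) <= sp$df))
})

test_that("default parameters give 5-s windows stepped by 0.1 s", {
  p <- spectral_params()
  expect_equal(p$window_s, 5)
  expect_equal(p$step_s, 0.1)
  expect_equal(p$time_bandwidth, 3)
  expect_equal(p$n_tapers, 5)
  fs <- 200
  x <- rnorm(fs * 12)
  sp <- multitaper_spectrogram(x, fs, spectral_params())
  expect_equal(diff(sp$times)[1], 0.1, tolerance = 1e-9)
  expect_equal(sp$window_s, 5)
})

test_that("white-noise spectrum matches an averaged-periodogram oracle", {
  fs <- 200
  set.seed(42)
  x <- rnorm(fs * 600)
  sp <- multitaper_spectrogram(x, fs, spectral_params(step_s = 2.5,
                                                      band_limit = c(0, 90)))
  mt_mean <- colMeans(sp$power)
  # oracle: boxcar periodograms on disjoint 5-s segments, same draw
  nwin <- fs * 5
  segs <- matrix(x[seq_len((length(x) %/% nwin) * nwin)], nrow = nwin)
  pg <- apply(segs, 2, function(s) {
    X <- fft(s)[seq_len(nwin %/% 2 + 1)]
    (Mod(X)^2 / (fs * nwin)) * c(1, rep(2, nwin %/% 2 - 1), 1)
  })
  freqs_o <- (0:(nwin %/% 2)) * fs / nwin
  keep <- freqs_o <= 90
  oracle <- rowMeans(pg)[keep]
  # compare band-averaged levels (flat spectrum)
  expect_lt(abs(mean(mt_mean) / mean(oracle) - 1), 0.2)
  expect_lt(stats::sd(mt_mean) / mean(mt_mean), 0.2)
})

test_that("band powers respect band membership and zero input", {
  fs <- 250
  x <- sin(2 * pi * 6 * (0:(fs * 100 - 1)) / fs)
  spec <- multitaper_spectrogram(x, fs, spectral_params(step_s = 2.5,
                                                        band_limit = c(0, 100)))
  bp <- epoch_band_powers(spec, NULL, 5)
  five <- bp[c("delta", "theta", "alpha", "beta", "gamma")]
  expect_true(all(apply(five, 1, which.max) == 2))  # theta wins everywhere
  bp0 <- epoch_band_powers(
    multitaper_spectrogram(numeric(fs * 20), fs,
                           spectral_params(step_s = 2.5)), NULL, 5)
  expect_true(all(bp0$delta == 0 & bp0$gamma == 0))
})

test_that("delta power of a 3 Hz tone matches a band-pass RMS oracle", {
  fs <- 500
  x <- 3 * sin(2 * pi * 3 * (0:(fs * 120 - 1)) / fs)
  spec <- multitaper_spectrogram(x, fs, spectral_params(step_s = 2.5))
  bp <- epoch_band_powers(spec, NULL, 5)
  # oracle: RMS^2 of the 2-4 Hz band-passed signal (the tone passes whole)
  bf <- signal::butter(4, c(2, 4) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  oracle <- mean(y^2)
  expect_lt(abs(median(bp$delta) / oracle - 1), 0.1)
})

test_that("robust_scale implements the SD-from-the-median definition", {
  expect_equal(robust_scale(c(1, 1, 1)), list(median = 1, s_med = 0))
  rs <- robust_scale(c(0, 0, 0, 4))
  expect_equal(rs$median, 0)
  expect_equal(rs$s_med, 2)
  # symmetric sample with median = mean: s_med equals population SD
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(robust_scale(x)$s_med, sqrt(mean((x - mean(x))^2)))
  expect_error(robust_scale(numeric()), "empty")
})

test_that("band powers scale with amplitude squared and stay below total", {
  fs <- 250
  set.seed(7)
  x <- rnorm(fs * 60)
  p1 <- epoch_band_powers(multitaper_spectrogram(x, fs,
    spectral_params(step_s = 2.5)), NULL, 5)
  p2 <- epoch_band_powers(multitaper_spectrogram(2 * x, fs,
    spectral_params(step_s = 2.5)), NULL, 5)
  for (b in c("delta", "theta", "alpha", "beta", "gamma"))
    expect_equal(p2[[b]], 4 * p1[[b]], tolerance = 1e-8)
  # the five bands have gaps, so their sum is below the 0-125 Hz total
  spec <- multitaper_spectrogram(x, fs, spectral_params(step_s = 2.5))
  total <- rowSums(spec$power) * spec$df
  five_sum <- rowSums(as.matrix(p1[c("delta", "theta", "alpha",
                                     "beta", "gamma")]))
  frames_per_epoch <- tapply(total, floor(spec$times / 5) + 1, mean)
  expect_true(all(five_sum <= frames_per_epoch[seq_along(five_sum)] + 1e-9))
})

test_that("short signals and bad parameters are rejected", {
  expect_error(multitaper_spectrogram(rnorm(100), 500, spectral_params()),
               "shorter")
  expect_error(spectral_params(window_s = 1, step_s = 2), "window_s")
  sp <- multitaper_spectrogram(rnorm(5000), 500, spectral_params(step_s = 2.5))
  expect_error(epoch_band_powers(sp, NULL, epoch_len_s = 1), "step")
})
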