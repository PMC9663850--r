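test_that("the 10-20 Hz band-pass keeps the passband and kills the stopband", {
  fs <- 500
  t <- (0:(fs * 30 - 1)) / fs
  x15 <- sin(2 * pi * 15 * t)
  expect_lt(abs(sd(bandpass_10_20(x15, fs)) / sd(x15) - 1), 0.05)
  # frequency-response oracle on the FIR kernel itself
  ord <- 2 * round(0.8 * fs)
  ker <- signal::fir1(ord, c(10, 20) / (fs / 2), type = "pass")
  H <- abs(fft(c(ker, rep(0, 2^15 - length(ker)))))
  f <- (0:(2^15 - 1)) * fs / 2^15
  att_db <- function(fr) -20 * log10(H[which.min(abs(f - fr))])
  expect_gte(att_db(8), 40)
  expect_gte(att_db(24), 40)
  # a 2 Hz tone is crushed by >= 40 dB
  x2 <- sin(2 * pi * 2 * t)
  expect_gte(-20 * log10(sd(bandpass_10_20(x2, fs)) / sd(x2)), 40)
  expect_error(bandpass_10_20(rnorm(1000), fs = 50), "too low")
})

# analytic spindle: Hann-enveloped carrier on a quiet baseline
make_burst <- function(carrier = 13, dur = 0.6, amp = 10, fs = 500,
                       total_s = 20, at = 10) {
  x <- numeric(fs * total_s)
  tt <- (0:(round(dur * fs) - 1)) / fs
  env <- 0.5 * (1 - cos(2 * pi * tt / dur))
  i0 <- round(at * fs) + 1
  x[i0:(i0 + length(tt) - 1)] <- amp * env * sin(2 * pi * carrier * tt)
  x
}

test_that("a planted burst inside NREM yields exactly one spindle", {
  fs <- 500
  set.seed(4)
  noise <- somnoblast:::band_noise(fs * 20, fs, 10, 20)  # sd 1
  x <- noise + make_burst(carrier = 13, dur = 0.6, amp = 8, fs = fs)
  h <- hypnogram(rep("NREM", 4), 5)
  sp <- detect_spindles(x, fs, h)
  expect_equal(nrow(sp), 1)
  expect_true(sp$start_s > 9.9 && sp$end_s < 10.7)
  expect_true(all(check_spindle_rules(sp)))
  expect_lt(abs(sp$intra_freq_hz - 13), 2.5)
  # the same burst with an AWAKE hypnogram is discarded
  h_awake <- hypnogram(rep("AWAKE", 4), 5)
  expect_equal(nrow(detect_spindles(x, fs, h_awake)), 0)
})

test_that("the three printed acceptance rules reject marginal groups", {
  fs <- 500
  h <- hypnogram(rep("NREM", 4), 5)
  # five selected peaks only (2.5 carrier cycles): rejected
  x5 <- make_burst(carrier = 12.5, dur = 0.21, amp = 50, fs = fs)
  sp5 <- detect_spindles(x5, fs, h, threshold_sd = 0.5)
  for (i in seq_len(nrow(sp5)))
    expect_gt(length(attr(sp5, "peaks")[[i]]), 5)
  # a 0.15-s burst can never span > 0.2 s
  x_short <- make_burst(carrier = 13, dur = 0.15, amp = 50, fs = fs)
  expect_equal(nrow(detect_spindles(x_short, fs, h, threshold_sd = 0.5)), 0)
  # two bursts 0.3 s apart are never merged
  x2 <- make_burst(13, 0.5, 30, fs, at = 10) +
    make_burst(13, 0.5, 30, fs, at = 10.8)
  sp2 <- detect_spindles(x2, fs, h, threshold_sd = 0.5)
  expect_equal(nrow(sp2), 2)
  expect_true(all(check_spindle_rules(sp2)))
})

test_that("feature formulas follow their definitions", {
  # intra-spindle frequency is exactly cycles/duration
  fs <- 500
  x <- make_burst(carrier = 14, dur = 0.5, amp = 40, fs = fs)
  h <- hypnogram(rep("NREM", 4), 5)
  sp <- detect_spindles(x, fs, h)
  expect_equal(sp$intra_freq_hz, sp$cycles / sp$duration_s)
  # symmetry of a Hann envelope is 0.5 up to one inter-peak interval
  expect_lt(abs(sp$symmetry - 0.5), (1 / 14) / sp$duration_s + 1e-9)
  # amplitude is max positive minus min negative extremum
  seg <- c(0, 30, 0, -28, 0, 25, 0, -20, 0)
  f <- spindle_features(seg, peak_times = c(0, 8) / 100, fs = 100)
  expect_equal(f$amplitude_uv, 58)
  # planted peak-to-trough recovered within 10%
  expect_lt(abs(sp$amplitude_uv / (2 * 40) - 1), 0.1)
  expect_error(spindle_features(numeric(), 1, 500), "empty")
})

test_that("spindle summary computes density per NREM second", {
  sp <- data.frame(subject = "s", start_s = seq(10, 120, by = 10),
                   end_s = seq(10.5, 120.5, by = 10))
  sp$duration_s <- 0.5; sp$amplitude_uv <- 20; sp$cycles <- 7
  sp$intra_freq_hz <- 14; sp$symmetry <- 0.5
  h <- hypnogram(rep("NREM", 240), 5)  # 1200 s of NREM
  s <- spindle_summary(sp, h, day = 1)
  expect_equal(s$count, 12)
  expect_equal(s$density_per_s, 0.01)
  s0 <- spindle_summary(sp[0, ], h, day = 1)
  expect_equal(s0$count, 0)
  expect_equal(s0$density_per_s, 0)
  expect_true(is.na(s0$mean_amplitude_uv))
  h_aw <- hypnogram(rep("AWAKE", 240), 5)
  expect_error(spindle_summary(sp, h_aw, 1), "NREM")
})

test_that("detected spindles always satisfy the stored-peak re-check", {
  fs <- 500
  for (s in 1:3) {
    set.seed(s)
    noise <- somnoblast:::band_noise(fs * 60, fs, 10, 20) * 2
    x <- noise +
      make_burst(12, 0.8, 16, fs, total_s = 60, at = 12) +
      make_burst(14, 0.7, 16, fs, total_s = 60, at = 40)
    h <- hypnogram(rep(c("NREM", "AWAKE"), each = 6), 5)
    sp <- detect_spindles(x, fs, h)
    if (nrow(sp)) {
      expect_true(all(check_spindle_rules(sp)))
      mid <- (sp$start_s + sp$end_s) / 2
      expect_true(all(h$labels[floor(mid / 5) + 1] == "NREM"))
      expect_equal(sp$intra_freq_hz, sp$cycles / sp$duration_s)
    }
  }
})
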