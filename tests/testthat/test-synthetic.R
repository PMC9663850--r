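test_that("hypnogram simulation is deterministic and epoch-aligned", {
  cfg <- sim_config(duration_h = 1)
  h1 <- simulate_hypnogram(cfg, 7)$hypnogram
  h2 <- simulate_hypnogram(cfg, 7)$hypnogram
  expect_identical(h1$labels, h2$labels)
  expect_equal(h1$epoch_len_s, 5)
  expect_equal(length(h1$labels), 720)
  h3 <- simulate_hypnogram(cfg, 8)$hypnogram
  expect_false(identical(h1$labels, h3$labels))
  # REM is entered only from NREM
  r <- rle(h1$labels)
  before_rem <- r$values[which(r$values == "REM") - 1]
  expect_true(all(before_rem == "NREM"))
})

test_that("state-time fractions match the semi-Markov closed form", {
  cfg <- sim_config(duration_h = 24)
  fr <- sapply(1:10, function(s)
    table(factor(simulate_hypnogram(cfg, s)$hypnogram$labels,
                 c("AWAKE", "NREM", "REM"))) / 17280)
  obs <- rowMeans(fr)
  expected <- (stationary_fractions(cfg, "light") +
                 stationary_fractions(cfg, "dark")) / 2
  for (s in names(expected))
    expect_lt(abs(obs[s] / expected[s] - 1), 0.10)
})

test_that("planted NREM epochs carry more delta power than awake ones", {
  fx <- sim_fixture(seed = 2, duration_h = 0.5)
  spec <- multitaper_spectrogram(fx$record$eeg, fx$record$fs,
                                 spectral_params(step_s = 2.5))
  bp <- epoch_band_powers(spec, NULL, 5)
  lab <- fx$hypnogram$labels
  dn <- bp$delta[lab == "NREM"]
  da <- bp$delta[lab == "AWAKE"]
  # pairwise dominance: >= 95% of NREM epochs beat the awake median
  expect_gte(mean(dn > median(da)), 0.95)
  expect_gte(mean(da < median(dn)), 0.95)
})

test_that("signal generation is reproducible and correctly sized", {
  cfg <- sim_config(duration_h = 0.1)
  h <- simulate_hypnogram(cfg, 3)$hypnogram
  s1 <- simulate_signals(h, cfg, 3)
  s2 <- simulate_signals(h, cfg, 3)
  expect_identical(s1$record$eeg, s2$record$eeg)
  expect_identical(s1$truth$spindles, s2$truth$spindles)
  expect_equal(s1$record$fs, 500)
  expect_equal(length(s1$record$eeg), 0.1 * 3600 * 500)
  expect_equal(length(s1$record$eeg), length(s1$record$emg))
})

test_that("planted spindles lie inside NREM and follow the Poisson rate", {
  fx <- sim_fixture(seed = 5, duration_h = 1)
  tr <- fx$truth$spindles
  lab <- fx$hypnogram$labels
  # every planted spindle wholly inside a NREM episode
  for (i in seq_len(nrow(tr))) {
    ep <- (floor(tr$start_s[i] / 5) + 1):(ceiling(tr$end_s[i] / 5))
    expect_true(all(lab[ep] == "NREM"))
  }
  nrem_s <- sum(lab == "NREM") * 5
  lambda <- fx$cfg$spindle$rate_per_s_nrem * nrem_s
  expect_lt(abs(nrow(tr) - lambda), 3 * sqrt(lambda) + 3)
})

test_that("behavior tables encode the planted effects and violations", {
  asn <- data.frame(
    subject_id = sprintf("s%02d", 1:40),
    label = rep(c("CONTROL", "SBI-HD"), each = 20))
  cfg <- sim_config()
  beh <- simulate_behavior(asn, cfg, seed = 11)
  fn <- filter_trials(beh$nor, "nor")
  ctrl <- grepl("CONTROL", asn$label[match(fn$included$subject_id,
                                           asn$subject_id)])
  pref <- nor_preference(fn$included)
  expect_gt(mean(pref[ctrl]), mean(pref[!ctrl]))
  # null effect: deficit multiplier 1 gives identical generating law
  cfg0 <- cfg
  cfg0$behavior$nor_pref_injured <- cfg0$behavior$nor_pref_control
  beh0 <- simulate_behavior(asn, cfg0, seed = 11)
  p0 <- nor_preference(beh0$nor)
  ctrl_all <- asn$label == "CONTROL"
  expect_gt(t.test(log(p0[ctrl_all]), log(p0[!ctrl_all]))$p.value, 0.01)
  # planted violation fraction behaves binomially
  cfgv <- sim_config()
  cfgv$behavior$violation_frac <- 0.2
  asn_big <- data.frame(subject_id = sprintf("t%03d", 1:100),
                        label = rep("CONTROL", 100))
  behv <- simulate_behavior(asn_big, cfgv, seed = 13)
  n_exc <- nrow(filter_trials(behv$nor, "nor")$excluded)
  expect_lt(abs(n_exc - 20), 8 + 1e-9)
  # motor deficit scales run times down for injured subjects
  ag <- aggregate_motor(beh$motor[beh$motor$kind == "rotarod", ])
  psd <- ag$per_subject_day
  hd <- grepl("SBI", asn$label[match(psd$subject_id, asn$subject_id)])
  expect_gt(mean(psd$mean[!hd]), mean(psd$mean[hd]))
})

test_that("cohort simulation labels groups and applies the HD profile", {
  cfg <- sim_config(duration_h = 0.05)
  sim <- simulate_cohort(2, 2, 2, cfg, seed = 4)
  expect_equal(nrow(sim$subjects), 6)
  expect_equal(sum(sim$subjects$group == "HD"), 2)
  rec <- sim$records[[sim$subjects$subject_id[3]]]  # an HD subject
  expect_equal(rec$baseline$record$day_index, 0L)
  expect_equal(rec$post$record$day_index, 2L)
  # default group sizes mirror the published cohort design
  frm <- formals(simulate_cohort)
  expect_equal(frm$n_control, 11)
  expect_equal(frm$n_HD, 8)
  expect_equal(frm$n_LD, 8)
  # HD delta/alpha power multiplier ratio is 1.5/0.7
  p <- sim_config(injury = "HD")
  prof <- p$injury_profiles$HD
  expect_equal(unname(prof$band_mult["delta"] / prof$band_mult["alpha"]),
               1.5 / 0.7)
})
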