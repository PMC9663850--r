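test_that("threshold calibration matches hand-computed median + k s_med", {
  # gamma/delta series {0.8, 1.2, 0.8, 1.2}: median 1, s_med 0.2
  bp <- make_bp(4, delta = 1, gamma = c(0.8, 1.2, 0.8, 1.2), emg = 1)
  th <- calibrate_thresholds(bp, window_s = 20)
  expect_equal(th$awake_gd, 1 + 0.5 * 0.2)
  # delta/EMG series {1.5, 2.5, 1.5, 2.5}: median 2, s_med 0.5 -> 2.5
  bp2 <- make_bp(4, delta = c(1.5, 2.5, 1.5, 2.5), emg = 1)
  th2 <- calibrate_thresholds(bp2, window_s = 20)
  expect_equal(th2$nrem_de, 2.5)
  # constant ratios: every cut collapses onto the constant
  bp3 <- make_bp(6, delta = 2, gamma = 4, emg = 1)
  th3 <- calibrate_thresholds(bp3, window_s = 30)
  expect_equal(th3$awake_gd, 2)
  expect_error(calibrate_thresholds(bp3, window_s = 1000), "shorter")
})

test_that("classification follows the strict precedence hierarchy", {
  th <- structure(list(awake_gd = 1, awake_emg = 10, nrem_de = 2,
                       rem_tde = 0.5, calibration_window_s = 3600,
                       rem_k = 1), class = "sb_thresholds")
  # epoch 1: awake (gd 4 > 1, emg 20 > 10); epoch 2: NREM (de 5 > 2);
  # epoch 3: REM; epoch 4: nothing fires
  bp <- make_bp(4,
                delta = c(1, 5, 0.5, 1),
                theta = c(1, 1, 2, 0.1),
                gamma = c(4, 1, 0.2, 0.5),
                emg = c(20, 1, 1, 1))
  h <- classify_epochs(bp, th)
  expect_equal(h$labels, c("AWAKE", "NREM", "REM", "UNDETECTABLE"))
  # all-zero powers: no rule fires after division guards
  h0 <- classify_epochs(make_bp(3, delta = 0, theta = 0, alpha = 0,
                                beta = 0, gamma = 0, emg = 0), th)
  expect_equal(unique(h0$labels), "UNDETECTABLE")
  # a missing epoch is UNDETECTABLE
  bpna <- make_bp(2, delta = 5, emg = 1)
  bpna$delta[2] <- NA
  expect_equal(classify_epochs(bpna, th)$labels[2], "UNDETECTABLE")
})

test_that("raising a cut never increases that state's count", {
  set.seed(11)
  bp <- make_bp(200, delta = exp(rnorm(200)), theta = exp(rnorm(200)),
                gamma = exp(rnorm(200)), emg = exp(rnorm(200)))
  th <- calibrate_thresholds(bp, window_s = 1000)
  n_awake <- function(t) sum(classify_epochs(bp, t)$labels == "AWAKE")
  n_nrem <- function(t) sum(classify_epochs(bp, t)$labels == "NREM")
  for (f in c(1.2, 2, 5)) {
    th_hi <- th; th_hi$awake_gd <- th$awake_gd * f
    expect_lte(n_awake(th_hi), n_awake(th))
    th_hi2 <- th; th_hi2$nrem_de <- th$nrem_de * f
    expect_lte(n_nrem(th_hi2), n_nrem(th))
  }
})

test_that("ratio rules are invariant to consistent power rescaling", {
  set.seed(12)
  bp <- make_bp(100, delta = exp(rnorm(100)), theta = exp(rnorm(100)),
                gamma = exp(rnorm(100)), emg = exp(rnorm(100)))
  th <- calibrate_thresholds(bp, 500)
  h1 <- classify_epochs(bp, th)
  # scaling all EEG band powers by c leaves gamma/delta unchanged and
  # scales delta/EMG and theta/(delta*EMG); rescale the cuts to match
  cc <- 7
  bp2 <- bp
  for (b in c("delta", "theta", "alpha", "beta", "gamma"))
    bp2[[b]] <- bp2[[b]] * cc
  th2 <- th
  th2$nrem_de <- th$nrem_de * cc
  th2$rem_tde <- th$rem_tde  # theta/(delta*emg): c cancels
  h2 <- classify_epochs(bp2, th2)
  expect_equal(h2$labels, h1$labels)
})

test_that("state metrics conserve time and count episodes by runs", {
  h <- hypnogram(rep("NREM", 17280), 5)  # 24 h of NREM
  m <- state_metrics(h)
  all_row <- m[m$day == "all" & m$phase == "all" & m$state == "NREM", ]
  expect_equal(all_row$total_s, 86400)
  expect_equal(all_row$n_episodes, 1L)
  expect_equal(all_row$mean_episode_s, 86400)
  zero <- m[m$day == "all" & m$phase == "all" & m$state == "REM", ]
  expect_equal(zero$total_s, 0)
  # strict alternation: every episode is one epoch
  h2 <- hypnogram(rep(c("AWAKE", "NREM"), 100), 5)
  m2 <- state_metrics(h2)
  a <- m2[m2$day == "all" & m2$phase == "all" & m2$state == "AWAKE", ]
  expect_equal(a$n_episodes, 100L)
  expect_equal(a$mean_episode_s, 5)
  # conservation for an arbitrary hypnogram
  set.seed(3)
  h3 <- hypnogram(sample(c("AWAKE", "NREM", "REM", "UNDETECTABLE"),
                         5000, replace = TRUE), 5)
  m3 <- state_metrics(h3)
  tot <- sum(m3$total_s[m3$day == "all" & m3$phase == "all"])
  expect_equal(tot, hypnogram_duration(h3))
  # light/dark split also conserves
  ld <- m3[m3$day == "all" & m3$phase %in% c("light", "dark"), ]
  expect_equal(sum(ld$total_s), hypnogram_duration(h3))
})

test_that("baseline normalization gives relative units", {
  expect_equal(normalize_to_baseline(240, c(200, 200)), 1.2)
  expect_equal(normalize_to_baseline(7, rep(7, 5)), 1)
  expect_error(normalize_to_baseline(1, c(-1, 1)), "zero")
})

test_that("light and dark phases follow the reverse-cycle clock", {
  # t0 09:00 is dark onset; 12 h later the light phase starts
  h <- hypnogram(rep("AWAKE", 17280), 5, t0 = "09:00")
  m <- state_metrics(h)
  dark <- m[m$day == "all" & m$phase == "dark" & m$state == "AWAKE", ]
  light <- m[m$day == "all" & m$phase == "light" & m$state == "AWAKE", ]
  expect_equal(dark$total_s, 43200)
  expect_equal(light$total_s, 43200)
})
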