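# Synthetic EEG/EMG/behavior generator with full ground truth.
#
# The EEG is a mixture of band-limited Gaussian noise components (one
# per canonical band, white noise band-pass filtered in the frequency
# domain and rescaled to unit RMS) whose amplitudes are modulated per
# 5-s epoch by the active
# state's profile, plus Hann-enveloped spindle bursts inserted as a
# Poisson process inside NREM episodes. The EMG is white noise scaled
# by a state-dependent muscle-tone amplitude. Because every staging
# rule is a band-power ratio, this construction gives transparent
# per-band ground truth: planted band power scales exactly with the
# squared state multiplier.
#
# State dynamics are a semi-Markov chain over AWAKE/NREM/REM in 5-s
# epochs with geometric dwell times; REM is entered only from NREM, and
# the awake dwell time is lengthened during the dark (active) phase.

#' Simulation configuration
#'
#' Returns the default study conditions, optionally overridden. The
#' defaults emulate a reverse-cycle mouse telemetry study: 500 Hz
#' sampling, 24-h records starting at dark onset (09:00), roughly 55-60%
#' total sleep time, strong state contrast in the band profiles
#' (delta-dominant NREM, theta-dominant REM, high-gamma/high-EMG wake),
#' 12.5 Hz spindles at 0.05 events per NREM second, and injury profiles
#' expressing the acute high-delta phenotype (HD: delta x1.5, alpha and
#' gamma x0.7, 20% longer sleep dwell, spindle carrier -0.4 Hz and
#' amplitude x0.8) or a pure spindle-slowing phenotype (LD: carrier
#' -0.3 Hz only).
#'
#' @param ... Named overrides of any top-level default (lists are
#'   merged recursively).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    fs = 500, epoch_len_s = 5, duration_h = 24, t0 = "09:00",
    injury = "none",
    # semi-Markov state model (dwell means in seconds)
    dwell_s = c(AWAKE = 180, NREM = 150, REM = 120),
    trans = list(AWAKE = c(NREM = 1),
                 NREM = c(AWAKE = 0.5, REM = 0.5),
                 REM = c(AWAKE = 0.8, NREM = 0.2)),
    dark_awake_dwell_mult = 1.15,
    # per-band RMS amplitude (microvolts) and state multipliers
    band_rms = c(delta = 15, theta = 12, alpha = 10, beta = 6, gamma = 5),
    state_mult = rbind(
      AWAKE = c(delta = 0.5, theta = 1.0, alpha = 2.0, beta = 2.0, gamma = 2.0),
      NREM  = c(delta = 2.8, theta = 0.8, alpha = 1.0, beta = 0.8, gamma = 0.6),
      REM   = c(delta = 0.5, theta = 2.2, alpha = 0.9, beta = 0.8, gamma = 0.9)),
    emg_rms = 15,
    emg_mult = c(AWAKE = 3, NREM = 0.4, REM = 0.3),
    spindle = list(rate_per_s_nrem = 0.05, carrier_hz = 12.5,
                   duration_mean_s = 0.6, duration_sd_s = 0.1,
                   amplitude_sd_mult = 4),
    injury_profiles = list(
      none = list(band_mult = c(), sleep_time_mult = 1,
                  carrier_shift_hz = 0, spindle_amp_mult = 1),
      HD = list(band_mult = c(delta = 1.5, alpha = 0.7, gamma = 0.7),
                sleep_time_mult = 1.2, carrier_shift_hz = -0.4,
                spindle_amp_mult = 0.8),
      LD = list(band_mult = c(), sleep_time_mult = 1,
                carrier_shift_hz = -0.3, spindle_amp_mult = 1)),
    behavior = list(
      nor_pref_control = 1.9, nor_pref_injured = 1.0,
      ymaze_ratio_control = 2.0, ymaze_ratio_injured = 1.2,
      rotarod_base_s = 40, rotarod_learn_s_per_day = 2,
      beam_base_seg_s = 1.0,
      motor_deficit = c(`SBI-HD` = 0.7, `SBI-LD` = 0.9),
      violation_frac = 0.1))
  over <- list(...)
  if (length(over)) {
    stopifnot(!is.null(names(over)), all(names(over) %in% names(cfg)))
    cfg <- utils::modifyList(cfg, over)
  }
  structure(cfg, class = "sim_config")
}

#' High-SNR spindle settings
#'
#' Replaces the spindle block of a configuration by the long, large,
#' sparse bursts used for detector validation: 1.5-s mean duration,
#' peak envelope 8x the NREM background SD in the 10-20 Hz band, 0.03
#' events per NREM second (sparse enough that events never merge).
#'
#' @param cfg A [sim_config()].
#' @return Modified `sim_config`.
#' @export
high_snr_spindles <- function(cfg = sim_config()) {
  cfg$spindle$duration_mean_s <- 1.5
  cfg$spindle$duration_sd_s <- 0.15
  cfg$spindle$amplitude_sd_mult <- 8
  cfg$spindle$rate_per_s_nrem <- 0.03
  cfg
}

active_profile <- function(cfg) cfg$injury_profiles[[cfg$injury]]

# band RMS with the active injury multipliers applied; the profile's
# multipliers are band-POWER ratios (delta x1.5 means 50% more delta
# power), so they enter the amplitude as square roots
injured_band_rms <- function(cfg) {
  rms <- cfg$band_rms
  bm <- active_profile(cfg)$band_mult
  if (length(bm)) rms[names(bm)] <- rms[names(bm)] * sqrt(bm)
  rms
}

#' Expected stationary state-time fractions
#'
#' Closed-form time fractions of the semi-Markov state model for a given
#' phase: the stationary distribution of the embedded transition chain
#' weighted by the (phase-adjusted) mean dwell times.
#'
#' @param cfg A [sim_config()].
#' @param phase `"light"` or `"dark"` (the awake dwell is multiplied by
#'   `dark_awake_dwell_mult` in the dark phase).
#' @return Named vector of AWAKE/NREM/REM time fractions summing to 1.
#' @export
stationary_fractions <- function(cfg, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  states <- c("AWAKE", "NREM", "REM")
  P <- matrix(0, 3, 3, dimnames = list(states, states))
  for (s in states) {
    w <- cfg$trans[[s]]
    P[s, names(w)] <- w / sum(w)
  }
  ev <- eigen(t(P))
  pi0 <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi0 <- pi0 / sum(pi0)
  dw <- cfg$dwell_s[states]
  sl <- active_profile(cfg)$sleep_time_mult
  dw[c("NREM", "REM")] <- dw[c("NREM", "REM")] * sl
  if (phase == "dark") dw["AWAKE"] <- dw["AWAKE"] * cfg$dark_awake_dwell_mult
  fr <- pi0 * dw
  fr / sum(fr)
}

#' Simulate a hypnogram
#'
#' Semi-Markov chain over AWAKE/NREM/REM in 5-s epochs: geometric dwell
#' times with the configured means (awake dwell lengthened in the dark
#' phase; NREM/REM dwell scaled by the injury profile's sleep-time
#' multiplier), transitions by the configured weights (REM reachable
#' only from NREM).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `hypnogram` (the planted truth) and `truth`
#'   (state fractions and the active injury profile).
#' @export
simulate_hypnogram <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  n_ep <- round(cfg$duration_h * 3600 / cfg$epoch_len_s)
  states <- c("AWAKE", "NREM", "REM")
  sl <- active_profile(cfg)$sleep_time_mult
  dwell_ep <- cfg$dwell_s / cfg$epoch_len_s
  dwell_ep[c("NREM", "REM")] <- dwell_ep[c("NREM", "REM")] * sl
  lab <- character(n_ep)
  fr0 <- stationary_fractions(cfg, "dark")
  cur <- sample(states, 1, prob = fr0)
  i <- 1L
  while (i <= n_ep) {
    m <- dwell_ep[[cur]]
    if (cur == "AWAKE" &&
        phase_of((i - 1) * cfg$epoch_len_s, cfg$t0) == "dark")
      m <- m * cfg$dark_awake_dwell_mult
    len <- stats::rgeom(1, 1 / m) + 1L
    j <- min(i + len - 1L, n_ep)
    lab[i:j] <- cur
    i <- j + 1L
    w <- cfg$trans[[cur]]
    cur <- if (length(w) == 1) names(w) else
      sample(names(w), 1, prob = w)
  }
  h <- hypnogram(lab, cfg$epoch_len_s, cfg$t0)
  list(hypnogram = h,
       truth = list(fractions = table(factor(lab, states)) / n_ep,
                    injury = cfg$injury))
}

# Background RMS of the 10-20 Hz band-passed trace implied by the
# profile: alpha contributes its (13-10)/(13-8) share, beta its
# (20-16)/(31-16) share (band components are approximately flat across
# their band). With per-state fractions this gives the whole-record SD,
# the same reference the detector's z-score uses; awake EEG carries the
# most 10-20 Hz activity, so this SD sits well above the NREM
# background, which keeps the NREM false-alarm rate low.
sigma_10_20 <- function(cfg, state_fracs = NULL) {
  rms <- injured_band_rms(cfg)
  per_state <- vapply(rownames(cfg$state_mult), function(s) {
    (rms[["alpha"]] * cfg$state_mult[s, "alpha"])^2 * (13 - 10) / (13 - 8) +
      (rms[["beta"]] * cfg$state_mult[s, "beta"])^2 * (20 - 16) / (31 - 16)
  }, numeric(1))
  if (is.null(state_fracs)) return(sqrt(per_state))
  sqrt(sum(per_state[names(state_fracs)] * state_fracs))
}

# Unit-RMS band-limited Gaussian noise: white noise filtered to an
# ideal band-pass, synthesized directly in the frequency domain
# (independent complex Gaussian coefficients on the in-band DFT bins,
# one inverse FFT). The in-band spectrum is exactly flat, which makes
# planted band powers transparent. `bands` is a list of c(low, high)
# pairs; pairs of bands share one complex transform (the real and
# imaginary parts of an asymmetric spectrum are independent noises).
band_noise_set <- function(n, fs, bands) {
  out <- vector("list", length(bands))
  names(out) <- names(bands)
  # 1-based DFT bin indices whose frequency lies in [low, high), f > 0
  bin_idx <- function(band) {
    lo <- max(1L, as.integer(ceiling(band[1] * n / fs)))
    hi <- min(n %/% 2, as.integer(ceiling(band[2] * n / fs)) - 1L)
    if (hi < lo) integer() else (lo:hi) + 1L
  }
  i <- 1L
  while (i <= length(bands)) {
    spec <- complex(length.out = n)
    k <- bin_idx(bands[[i]])
    z <- complex(real = stats::rnorm(length(k)),
                 imaginary = stats::rnorm(length(k)))
    spec[k] <- z
    spec[n + 2L - k] <- Conj(z)
    two <- i + 1L <= length(bands)
    if (two) {
      # second band rides on the anti-Hermitian part of the spectrum
      k2 <- bin_idx(bands[[i + 1L]])
      z2 <- complex(real = stats::rnorm(length(k2)),
                    imaginary = stats::rnorm(length(k2)))
      spec[k2] <- spec[k2] + 1i * z2
      spec[n + 2L - k2] <- spec[n + 2L - k2] + 1i * Conj(z2)
    }
    y <- stats::fft(spec, inverse = TRUE)
    rm(spec)
    if (n > 2e7) gc(verbose = FALSE)
    x1 <- Re(y)
    x2 <- if (two) Im(y) else NULL
    rm(y)
    out[[i]] <- x1 / stats::sd(x1)
    rm(x1)
    if (two) out[[i + 1L]] <- x2 / stats::sd(x2)
    i <- i + 2L
  }
  out
}

band_noise <- function(n, fs, low, high)
  band_noise_set(n, fs, list(c(low, high)))[[1]]

#' Simulate an EEG/EMG record for a planted hypnogram
#'
#' See the module description at the top of this file for the signal
#' model. Every planted spindle lies wholly inside a NREM episode; its
#' peak envelope amplitude is `amplitude_sd_mult` times the expected
#' whole-record SD of the 10-20 Hz band-passed trace (the same
#' reference the detector's z-score uses), times the injury profile's
#' spindle amplitude multiplier; its carrier is the configured
#' frequency plus the profile's carrier shift.
#'
#' @param h A planted [hypnogram()] (from [simulate_hypnogram()]).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param subject_id,day_index Metadata for the returned record.
#' @return List with `record` (a [signal_record()]) and `truth`
#'   (data frame of planted spindles: `start_s`, `end_s`, `carrier_hz`,
#'   `amplitude_uv`; plus the planted hypnogram).
#' @export
simulate_signals <- function(h, cfg = sim_config(), seed = 1,
                             subject_id = "sim", day_index = 1L) {
  stopifnot(inherits(h, "hypnogram"))
  set.seed(seed + 1L)
  fs <- cfg$fs
  spe <- round(cfg$epoch_len_s * fs)       # samples per epoch
  n <- length(h$labels) * spe
  rms <- injured_band_rms(cfg)
  spe_gain <- function(b)
    rep(rms[[b]] * cfg$state_mult[, b][match(h$labels,
                                             rownames(cfg$state_mult))],
        each = spe)
  bands <- eeg_bands()
  eeg <- numeric(n)
  # stream bands straight into the accumulator; on day-long records
  # take them one at a time to keep the peak working set small
  by <- if (n > 2e7) 1 else 2
  for (i in seq(1, length(bands), by = by)) {
    grp <- bands[i:min(i + by - 1, length(bands))]
    noise <- band_noise_set(n, fs, grp)
    for (b in names(grp)) {
      eeg <- eeg + spe_gain(b) * noise[[b]]
      noise[[b]] <- numeric(0)
    }
    rm(noise)
    if (n > 2e7) gc(verbose = FALSE)
  }
  # spindles: Poisson process within each NREM episode
  prof <- active_profile(cfg)
  sp <- cfg$spindle
  carrier <- sp$carrier_hz + prof$carrier_shift_hz
  fracs <- table(factor(h$labels, rownames(cfg$state_mult))) / length(h$labels)
  amp <- sp$amplitude_sd_mult * prof$spindle_amp_mult *
    sigma_10_20(cfg, c(fracs))
  r <- rle(h$labels)
  ep_end <- cumsum(r$lengths)
  ep_start <- ep_end - r$lengths
  truth_sp <- list()
  for (k in which(r$values == "NREM")) {
    e0 <- ep_start[k] * cfg$epoch_len_s
    e1 <- ep_end[k] * cfg$epoch_len_s
    n_sp <- stats::rpois(1, sp$rate_per_s_nrem * (e1 - e0))
    if (!n_sp) next
    for (q in seq_len(n_sp)) {
      d <- max(0.3, stats::rnorm(1, sp$duration_mean_s, sp$duration_sd_s))
      t0s <- stats::runif(1, e0, e1 - d)
      if (t0s + d > e1) next
      i0 <- floor(t0s * fs) + 1L
      len <- round(d * fs)
      if (i0 + len - 1L > n) next
      tt <- (0:(len - 1)) / fs
      env <- 0.5 * (1 - cos(2 * pi * tt / ((len - 1) / fs)))  # Hann, peak center
      phase <- stats::runif(1, 0, 2 * pi)
      eeg[i0:(i0 + len - 1L)] <- eeg[i0:(i0 + len - 1L)] +
        amp * env * sin(2 * pi * carrier * tt + phase)
      truth_sp[[length(truth_sp) + 1]] <-
        data.frame(start_s = t0s, end_s = t0s + d, carrier_hz = carrier,
                   amplitude_uv = amp)
    }
  }
  truth_sp <- if (length(truth_sp)) do.call(rbind, truth_sp) else
    data.frame(start_s = numeric(), end_s = numeric(),
               carrier_hz = numeric(), amplitude_uv = numeric())
  truth_sp <- truth_sp[order(truth_sp$start_s), , drop = FALSE]
  rownames(truth_sp) <- NULL
  emg <- cfg$emg_rms * rep(cfg$emg_mult[h$labels], each = spe) *
    stats::rnorm(n)
  rec <- signal_record(eeg, unname(emg), fs = fs, t0 = h$t0,
                       subject_id = subject_id, day_index = day_index)
  list(record = rec, truth = list(spindles = truth_sp, hypnogram = h))
}

#' Simulate a multi-subject cohort
#'
#' For every subject, a baseline record (no injury profile) and a
#' post-injury record with the group's profile applied, each with its
#' own planted hypnogram and spindles. Group sizes default to the
#' 11 control / 8 HD / 8 LD design.
#'
#' @param n_control,n_HD,n_LD Group sizes.
#' @param cfg A [sim_config()]; its `duration_h` applies to every
#'   record.
#' @param seed Integer seed (per-record sub-seeds are drawn from it).
#' @return List of class `sim_cohort`: `subjects` (data frame with
#'   `subject_id`, `group`), and per-subject `records` — each a list
#'   with `baseline` and `post` entries as returned by
#'   [simulate_signals()].
#' @export
simulate_cohort <- function(n_control = 11, n_HD = 8, n_LD = 8,
                            cfg = sim_config(), seed = 1) {
  subjects <- data.frame(
    subject_id = c(sprintf("ctrl%02d", seq_len(n_control)),
                   sprintf("hd%02d", seq_len(n_HD)),
                   sprintf("ld%02d", seq_len(n_LD))),
    group = c(rep("control", n_control), rep("HD", n_HD), rep("LD", n_LD)),
    stringsAsFactors = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(2^20, 2 * nrow(subjects))
  records <- vector("list", nrow(subjects))
  names(records) <- subjects$subject_id
  for (i in seq_len(nrow(subjects))) {
    base_cfg <- cfg; base_cfg$injury <- "none"
    post_cfg <- cfg
    post_cfg$injury <- switch(subjects$group[i],
                              control = "none", HD = "HD", LD = "LD")
    s1 <- sub_seeds[2 * i - 1]; s2 <- sub_seeds[2 * i]
    hb <- simulate_hypnogram(base_cfg, s1)
    hp <- simulate_hypnogram(post_cfg, s2)
    records[[i]] <- list(
      baseline = simulate_signals(hb$hypnogram, base_cfg, s1,
                                  subjects$subject_id[i], 0L),
      post = simulate_signals(hp$hypnogram, post_cfg, s2,
                              subjects$subject_id[i], 2L))
  }
  structure(list(subjects = subjects, records = records, cfg = cfg,
                 seed = seed),
            class = "sim_cohort")
}

#' Delta/alpha scores for a simulated cohort
#'
#' Runs the spectral + scoring pipeline over every subject of a
#' [simulate_cohort()] result: EEG spectrogram, per-epoch band powers,
#' and [delta_alpha_scores()] of the post record against the baseline
#' record. State epochs come from the planted hypnograms by default
#' (isolating the clustering from staging error) or from full
#' [stage_record()] staging.
#'
#' @param sim A `sim_cohort`.
#' @param step_s Spectrogram step used for the band powers.
#' @param use_planted_hypnogram Use planted state labels (default) or
#'   re-stage each record.
#' @return Data frame of per-subject scores (see
#'   [delta_alpha_scores()]).
#' @export
score_simulated_cohort <- function(sim, step_s = 2.5,
                                   use_planted_hypnogram = TRUE) {
  stopifnot(inherits(sim, "sim_cohort"))
  one <- function(entry) {
    rec <- entry$record
    if (use_planted_hypnogram) {
      spec <- multitaper_spectrogram(rec$eeg, rec$fs,
        spectral_params(step_s = step_s, band_limit = c(0, 150)))
      bp <- epoch_band_powers(spec, NULL, entry$truth$hypnogram$epoch_len_s)
      list(bp = bp, h = entry$truth$hypnogram)
    } else {
      st <- stage_record(rec, step_s = step_s)
      list(bp = st$band_powers, h = st$hypnogram)
    }
  }
  do.call(rbind, lapply(sim$subjects$subject_id, function(id) {
    b <- one(sim$records[[id]]$baseline)
    p <- one(sim$records[[id]]$post)
    delta_alpha_scores(p$bp, p$h, b$bp, b$h, subject_id = id,
                       day_index = sim$records[[id]]$post$record$day_index)
  }))
}

#' Simulate behavioral trial tables
#'
#' NOR, Y-maze and motor (rotarod + beam) trials for a labeled cohort.
#' Control NOR preference is drawn around 1.9 and injured around 1.0
#' (the day-1 object times are unbiased, so the planted preference is
#' expressed through the day-2 time ratio); Y-maze new/familiar ratios
#' around 2.0 (control) and 1.2 (injured); rotarod run times follow a
#' per-day learning trend scaled by the group's deficit multiplier, as
#' do beam velocities. A configured fraction of NOR/Y-maze trials is
#' forced to violate one exclusion rule (short exploration, short arm
#' time, few visits, or tracking loss) to exercise [filter_trials()].
#'
#' @param assignment Data frame with `subject_id` and `label`
#'   (`CONTROL`, `SBI-HD`, `SBI-LD`).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param n_days Days of motor testing (default 5).
#' @return List with `nor`, `ymaze`, `motor` trial data frames and a
#'   `truth` list of the planted effect sizes.
#' @export
simulate_behavior <- function(assignment, cfg = sim_config(), seed = 1,
                              n_days = 5) {
  stopifnot(all(c("subject_id", "label") %in% names(assignment)))
  set.seed(seed)
  bh <- cfg$behavior
  n <- nrow(assignment)
  injured <- assignment$label != "CONTROL"
  rpos <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0.05 * mean)

  nor_target <- ifelse(injured, bh$nor_pref_injured, bh$nor_pref_control) *
    exp(stats::rnorm(n, 0, 0.15))
  time1 <- rpos(n, 25, 5)
  time2 <- rpos(n, 25, 5)
  time4 <- rpos(n, 15, 3)
  nor <- data.frame(subject_id = assignment$subject_id,
                    time1 = time1, time2 = time2,
                    time3 = nor_target * time4 * time1 / time2,
                    time4 = time4, tracking_loss_frac = stats::runif(n, 0, 0.05))
  ym_target <- ifelse(injured, bh$ymaze_ratio_injured, bh$ymaze_ratio_control) *
    exp(stats::rnorm(n, 0, 0.15))
  fam <- rpos(n, 40, 8)
  ymaze <- data.frame(subject_id = assignment$subject_id,
                      time_new = ym_target * fam, time_familiar = fam,
                      visits_total = stats::rpois(n, 12) + 2L,
                      tracking_loss_frac = stats::runif(n, 0, 0.05))
  # planted exclusion-rule violations
  viol <- function(df, fix) {
    hit <- which(stats::runif(nrow(df)) < bh$violation_frac)
    if (length(hit)) df[hit, ] <- fix(df[hit, , drop = FALSE])
    list(df = df, n = length(hit))
  }
  vn <- viol(nor, function(d) { sc <- 8 / (d$time3 + d$time4)
    d$time3 <- d$time3 * sc; d$time4 <- d$time4 * sc; d })
  nor <- vn$df
  vy <- viol(ymaze, function(d) {
    mode <- sample(1:3, nrow(d), replace = TRUE)
    d$time_new[mode == 1] <- stats::runif(sum(mode == 1), 1, 14)
    d$visits_total[mode == 2] <- sample(0:6, sum(mode == 2), replace = TRUE)
    d$tracking_loss_frac[mode == 3] <- stats::runif(sum(mode == 3), 0.11, 0.4)
    d })
  ymaze <- vy$df
  deficit <- ifelse(injured,
                    bh$motor_deficit[assignment$label], 1)
  motor <- do.call(rbind, lapply(seq_len(n), function(i) {
    days <- rep(seq_len(n_days), each = 5)
    run <- (bh$rotarod_base_s + bh$rotarod_learn_s_per_day * (days - 1)) *
      deficit[i] * exp(stats::rnorm(length(days), 0, 0.08))
    beam_days <- rep(seq_len(n_days), each = 3)
    beam <- bh$beam_base_seg_s * deficit[i] *
      exp(stats::rnorm(length(beam_days), 0, 0.1))
    rbind(data.frame(subject_id = assignment$subject_id[i],
                     day_index = days, kind = "rotarod", value = run),
          data.frame(subject_id = assignment$subject_id[i],
                     day_index = beam_days, kind = "beam", value = beam))
  }))
  list(nor = nor, ymaze = ymaze, motor = motor,
       truth = list(nor_pref = c(control = bh$nor_pref_control,
                                 injured = bh$nor_pref_injured),
                    ymaze_ratio = c(control = bh$ymaze_ratio_control,
                                    injured = bh$ymaze_ratio_injured),
                    motor_deficit = bh$motor_deficit,
                    violation_frac = bh$violation_frac,
                    n_violations = c(nor = vn$n, ymaze = vy$n)))
}
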