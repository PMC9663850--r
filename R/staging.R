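# Rule-based 5-s epoch staging with thresholds calibrated on robust
# scale statistics, plus state-duration metrics and baseline
# normalization.
#
# The classifier is a strict precedence hierarchy on band-power ratios:
#   1. AWAKE  if gamma/delta > awake_gd  AND  emg_power > awake_emg
#   2. NREM   if delta/emg   > nrem_de
#   3. REM    if theta/(delta*emg) > rem_tde
#   4. UNDETECTABLE otherwise (including epochs with missing powers).
# Cuts are median + k * s_med of the corresponding ratio over a
# calibration window (first hour by default); the awake EMG cut is the
# calibration-window median EMG power.

# denominator guard: floor at 1e-12 x the record median of the quantity
floor_den <- function(x) {
  med <- stats::median(x[is.finite(x)], na.rm = TRUE)
  if (!is.finite(med)) med <- 0
  pmax(x, 1e-12 * med)
}

staging_ratios <- function(bp) {
  list(gd = bp$gamma / floor_den(bp$delta),
       de = bp$delta / floor_den(bp$emg_power),
       tde = bp$theta / floor_den(bp$delta * bp$emg_power))
}

#' Calibrate staging thresholds
#'
#' Computes the four classification cuts over the epochs whose start lies
#' inside the calibration window (by default the first hour of the
#' record):
#' \itemize{
#'   \item `awake_gd`  = median + 0.5 s_med of gamma/delta,
#'   \item `awake_emg` = median EMG power,
#'   \item `nrem_de`   = median + 1.0 s_med of delta/EMG,
#'   \item `rem_tde`   = median + `rem_k` s_med of theta/(delta x EMG).
#' }
#' `s_med` is the standard deviation from the median, [robust_scale()].
#' The REM multiplier is exposed because this cut is the least
#' standardized in practice (commonly hand-tuned).
#'
#' @param bp A `band_power_table`.
#' @param window_s Calibration window in seconds (default 3600); the
#'   record must span at least this long.
#' @param rem_k REM threshold multiplier (default 1).
#' @return An object of class `sb_thresholds`.
#' @export
calibrate_thresholds <- function(bp, window_s = 3600, rem_k = 1) {
  stopifnot(inherits(bp, "data.frame"), window_s > 0)
  L <- attr(bp, "epoch_len_s")
  if (is.null(L)) L <- 5
  if (max(bp$start_s) + L < window_s)
    stop("calibrate_thresholds: record shorter than the calibration window")
  cal <- bp[bp$start_s < window_s, , drop = FALSE]
  r <- staging_ratios(cal)
  cut_at <- function(x, k) {
    s <- robust_scale(x)
    s$median + k * s$s_med
  }
  structure(list(awake_gd = cut_at(r$gd, 0.5),
                 awake_emg = stats::median(cal$emg_power, na.rm = TRUE),
                 nrem_de = cut_at(r$de, 1),
                 rem_tde = cut_at(r$tde, rem_k),
                 calibration_window_s = window_s, rem_k = rem_k),
            class = "sb_thresholds")
}

#' @export
print.sb_thresholds <- function(x, ...) {
  cat(sprintf(paste0("staging thresholds (calibrated over %g s):\n",
                     "  awake: gamma/delta > %.4g and EMG > %.4g\n",
                     "  NREM:  delta/EMG > %.4g\n",
                     "  REM:   theta/(delta*EMG) > %.4g (k = %g)\n"),
              x$calibration_window_s, x$awake_gd, x$awake_emg,
              x$nrem_de, x$rem_tde, x$rem_k))
  invisible(x)
}

#' Classify epochs into AWAKE/NREM/REM/UNDETECTABLE
#'
#' Applies the precedence rules described in [calibrate_thresholds()].
#' Epochs with missing band powers, and epochs for which no rule fires,
#' are labeled UNDETECTABLE.
#'
#' @param bp A `band_power_table`.
#' @param th An `sb_thresholds` object.
#' @param t0 Clock time of the first epoch for the returned hypnogram.
#' @return A [hypnogram()].
#' @export
classify_epochs <- function(bp, th, t0 = "09:00") {
  stopifnot(inherits(th, "sb_thresholds"))
  r <- staging_ratios(bp)
  gt <- function(x, cut) !is.na(x) & is.finite(x) & x > cut
  lab <- rep("UNDETECTABLE", nrow(bp))
  awake <- gt(r$gd, th$awake_gd) & gt(bp$emg_power, th$awake_emg)
  nrem <- !awake & gt(r$de, th$nrem_de)
  rem <- !awake & !nrem & gt(r$tde, th$rem_tde)
  lab[awake] <- "AWAKE"
  lab[nrem] <- "NREM"
  lab[rem] <- "REM"
  L <- attr(bp, "epoch_len_s")
  if (is.null(L)) L <- 5
  hypnogram(lab, epoch_len_s = L, t0 = t0)
}

#' State-duration metrics
#'
#' For every state, total time, episode count and mean episode duration,
#' overall and split by light/dark phase and 24-h day. An episode is a
#' maximal run of identical labels; runs are split at day and phase
#' boundaries within the corresponding rows, so episode counts in a cell
#' refer to runs inside that cell.
#'
#' @param h A [hypnogram()].
#' @return Data frame with columns `day` ("all" or day number), `phase`
#'   ("all", "light", "dark"), `state`, `total_s`, `n_episodes`,
#'   `mean_episode_s`.
#' @export
state_metrics <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  n <- length(h$labels)
  if (!n)
    return(data.frame(day = character(), phase = character(),
                      state = character(), total_s = numeric(),
                      n_episodes = integer(), mean_episode_s = numeric()))
  starts <- (seq_len(n) - 1) * h$epoch_len_s
  day <- floor(starts / 86400) + 1
  ph <- phase_of(starts, h$t0)
  cell_stats <- function(sel) {
    lab <- h$labels[sel]
    r <- rle(lab)
    do.call(rbind, lapply(.sb_states, function(s) {
      runs <- r$lengths[r$values == s]
      tot <- sum(lab == s) * h$epoch_len_s
      data.frame(state = s, total_s = tot, n_episodes = length(runs),
                 mean_episode_s = if (length(runs))
                   mean(runs) * h$epoch_len_s else NA_real_)
    }))
  }
  grid <- rbind(data.frame(day = "all", phase = "all"),
                expand.grid(day = "all", phase = c("light", "dark"),
                            stringsAsFactors = FALSE),
                expand.grid(day = as.character(sort(unique(day))),
                            phase = c("all", "light", "dark"),
                            stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- rep(TRUE, n)
    if (grid$day[i] != "all") sel <- sel & day == as.numeric(grid$day[i])
    if (grid$phase[i] != "all") sel <- sel & ph == grid$phase[i]
    if (!any(sel)) return(NULL)
    cbind(day = grid$day[i], phase = grid$phase[i], cell_stats(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Normalize a value to a pre-injury baseline
#'
#' Expresses `value` in relative units (rel.un.): `value /
#' mean(baseline_values)`. A value of 1.17 means 17% above the subject's
#' own pre-injury baseline.
#'
#' @param value Numeric value(s) to normalize.
#' @param baseline_values Baseline sample; its mean must be non-zero.
#' @return `value / mean(baseline_values)`.
#' @export
normalize_to_baseline <- function(value, baseline_values) {
  m <- mean(baseline_values, na.rm = TRUE)
  if (!is.finite(m) || m == 0)
    stop("normalize_to_baseline: baseline mean is zero or undefined")
  value / m
}

#' Staging quality-control summary
#'
#' Automated stand-in for visual inspection: per-state fractions, the
#' fraction of UNDETECTABLE epochs, and the epoch-to-epoch transition
#' matrix.
#'
#' @param h A [hypnogram()].
#' @return List with `fractions`, `frac_undetectable`, `transitions`.
#' @export
staging_qc <- function(h) {
  f <- factor(h$labels, levels = .sb_states)
  n <- length(h$labels)
  tr <- if (n > 1) table(from = f[-n], to = f[-1]) else
    table(from = factor(character(), .sb_states),
          to = factor(character(), .sb_states))
  list(fractions = stats::setNames(as.numeric(table(f)) / max(n, 1),
                                   .sb_states),
       frac_undetectable = mean(h$labels == "UNDETECTABLE"),
       transitions = tr)
}

#' Stage a record end to end
#'
#' Convenience driver: multitaper spectrograms for EEG (0-150 Hz) and EMG
#' (5-170 Hz), per-epoch band powers, threshold calibration on the first
#' hour (or the whole record if shorter) and epoch classification.
#' The spectrogram step defaults to 2.5 s here: band powers are averaged
#' within 5-s epochs, so the 0.1-s step of the raw spectrogram default
#' adds no information to staging, only runtime.
#'
#' @param rec A [signal_record()].
#' @param epoch_len_s Epoch length in seconds.
#' @param step_s Spectrogram step in seconds.
#' @param calibration_window_s Calibration window in seconds; `NULL`
#'   (the default) calibrates on the whole record. The median + k s_med
#'   cuts are composition statistics, and the state composition of a
#'   single hour varies a lot from hour to hour (a 1-h window holds only
#'   a few dozen episodes), so whole-record calibration is markedly more
#'   stable; pass 3600 for classical first-hour calibration.
#' @param rem_k REM threshold multiplier.
#' @return List of class `sb_staging`: `hypnogram`, `band_powers`,
#'   `thresholds`, `qc`.
#' @export
stage_record <- function(rec, epoch_len_s = 5, step_s = 2.5,
                         calibration_window_s = NULL, rem_k = 1) {
  stopifnot(inherits(rec, "signal_record"))
  dur <- record_duration(rec)
  if (is.null(calibration_window_s)) calibration_window_s <- dur
  eeg_spec <- multitaper_spectrogram(rec$eeg, rec$fs,
    spectral_params(step_s = step_s, band_limit = c(0, 150)))
  emg_spec <- multitaper_spectrogram(rec$emg, rec$fs,
    spectral_params(step_s = step_s, band_limit = c(5, 170)))
  bp <- epoch_band_powers(eeg_spec, emg_spec, epoch_len_s)
  th <- calibrate_thresholds(bp, min(calibration_window_s, dur), rem_k)
  h <- classify_epochs(bp, th, t0 = rec$t0)
  structure(list(hypnogram = h, band_powers = bp, thresholds = th,
                 qc = staging_qc(h)),
            class = "sb_staging")
}
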