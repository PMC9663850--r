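# NREM sleep-spindle detection on 10-20 Hz band-passed EEG and the five
# per-event features (amplitude, cycles, intra-spindle frequency,
# symmetry, duration) plus density summaries.
#
# "Peaks" throughout are signed local extrema of the band-passed trace:
# the amplitude definition (max positive minus min negative peak) only
# makes sense on a signed oscillation, not on an envelope. Selected
# peaks are extrema whose z-score magnitude exceeds the threshold on the
# whole-record distribution of the band-passed trace.

#' Zero-phase 10-20 Hz band-pass
#'
#' Linear-phase FIR band-pass (Hamming-window design) applied by FFT
#' circular convolution with the kernel centered at lag zero, i.e. exact
#' zero phase with output length equal to input length. The kernel order
#' gives stopband attenuation of at least 40 dB by 8 Hz and 24 Hz.
#'
#' @param eeg Numeric EEG trace (microvolts).
#' @param fs Sampling rate in Hz; must be at least 100.
#' @param low,high Passband edges in Hz (default 10-20).
#' @return Filtered trace, same length and units as the input.
#' @export
bandpass_10_20 <- function(eeg, fs, low = 10, high = 20) {
  if (fs < 100)
    stop("bandpass_10_20: sampling rate too low for a 10-20 Hz band")
  n <- length(eeg)
  ord <- 2 * round(0.8 * fs)            # 801 taps at 500 Hz
  if (n <= 2 * ord)                      # short inputs: shrink the kernel
    ord <- max(50L, 2L * (n %/% 5L))
  h <- signal::fir1(ord, c(low, high) / (fs / 2), type = "pass")
  m <- ord / 2
  # overlap-save FFT convolution with the kernel centered at lag 0:
  # exact zero phase, constant memory in blocks regardless of record
  # length
  N <- 2^20
  while (N > 4 * (ord + 1) && N / 4 > n + ord) N <- N / 2
  hh <- c(h[(m + 1):(ord + 1)], rep(0, N - ord - 1), h[1:m])
  H <- stats::fft(hh)
  step <- N - ord
  out <- numeric(n)
  start <- 1L
  while (start <= n) {
    lo <- start - m
    hi <- start + N - m - 1L
    chunk <- numeric(N)
    src <- max(1L, lo):min(n, hi)
    chunk[src - lo + 1L] <- eeg[src]
    y <- Re(stats::fft(stats::fft(chunk) * H, inverse = TRUE)) / N
    nvalid <- min(step, n - start + 1L)
    out[start:(start + nvalid - 1L)] <- y[(m + 1L):(m + nvalid)]
    start <- start + step
  }
  out
}

# indices of local extrema (sign change of the first difference)
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # carry signs across flat spots so plateaus yield a single extremum
  nz <- s != 0
  if (!any(nz)) return(integer())
  s <- s[nz]
  idx <- which(nz)
  which(diff(s) != 0) |> (\(k) idx[k] + 1L)()
}

#' Detect NREM sleep spindles
#'
#' Z-scores the band-passed trace over the whole record, takes local
#' extrema with |z| > `threshold_sd` as selected peaks, groups
#' consecutive selected peaks whose successive gaps are all shorter than
#' `max_gap_s`, and accepts a group as a spindle iff it has more than
#' `min_peaks` selected peaks and spans more than `min_span_s` from
#' first to last peak. Events are then restricted to those whose
#' midpoint falls in a NREM epoch of `h`. Event features are computed
#' with [spindle_features()] on the unnormalized (microvolt) trace.
#'
#' @param filtered Output of [bandpass_10_20()] for the record.
#' @param fs Sampling rate in Hz.
#' @param h The record's [hypnogram()]; its duration must match the
#'   trace duration to within one epoch.
#' @param threshold_sd Peak selection threshold in SD units (default 2).
#' @param max_gap_s Maximum inter-peak gap within one spindle (default
#'   0.16 s; groups are split at gaps >= this).
#' @param min_peaks Minimum selected-peak count is `min_peaks + 1`
#'   ("more than five", default 5).
#' @param min_span_s Minimum first-to-last-peak span (default 0.2 s,
#'   strict).
#' @param cycles_all If `TRUE` (default) the cycle count uses all
#'   positive local maxima within the event span; if `FALSE`, only
#'   selected (supra-threshold) ones.
#' @param subject Subject id stored in the output table.
#' @return A `spindle_table` data frame with columns `subject`,
#'   `start_s`, `end_s`, `duration_s`, `amplitude_uv`, `cycles`,
#'   `intra_freq_hz`, `symmetry`; the selected-peak times of each event
#'   are kept in `attr(, "peaks")` so the acceptance rules can be
#'   re-checked exactly.
#' @export
detect_spindles <- function(filtered, fs, h, threshold_sd = 2,
                            max_gap_s = 0.16, min_peaks = 5,
                            min_span_s = 0.2, cycles_all = TRUE,
                            subject = NA_character_) {
  stopifnot(inherits(h, "hypnogram"))
  n <- length(filtered)
  if (abs(n / fs - hypnogram_duration(h)) > h$epoch_len_s)
    stop("detect_spindles: trace and hypnogram durations disagree")
  z <- (filtered - mean(filtered)) / stats::sd(filtered)
  ext <- local_extrema(filtered)
  sel <- ext[abs(z[ext]) > threshold_sd]
  empty <- spindle_table(NULL, subject)
  if (length(sel) < 2) return(empty)
  tsel <- (sel - 1) / fs
  grp <- cumsum(c(1, diff(tsel) >= max_gap_s))
  rows <- list()
  peaks <- list()
  for (g in split(seq_along(sel), grp)) {
    if (length(g) <= min_peaks) next
    i1 <- sel[g[1]]
    i2 <- sel[g[length(g)]]
    span <- (i2 - i1) / fs
    if (span <= min_span_s) next
    mid <- ((i1 + i2) / 2 - 1) / fs
    ep <- floor(mid / h$epoch_len_s) + 1
    if (ep < 1 || ep > length(h$labels) || h$labels[ep] != "NREM") next
    pk <- tsel[g]
    f <- spindle_features(filtered[i1:i2], pk, fs,
                          all_extrema = cycles_all)
    rows[[length(rows) + 1]] <-
      data.frame(subject = subject, start_s = pk[1], end_s = pk[length(pk)],
                 duration_s = f$duration_s, amplitude_uv = f$amplitude_uv,
                 cycles = f$cycles, intra_freq_hz = f$intra_freq_hz,
                 symmetry = f$symmetry)
    peaks[[length(peaks) + 1]] <- pk
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  o <- order(out$start_s)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "peaks") <- peaks[o]
  class(out) <- c("spindle_table", "data.frame")
  out
}

spindle_table <- function(df, subject = NA_character_) {
  if (is.null(df))
    df <- data.frame(subject = character(), start_s = numeric(),
                     end_s = numeric(), duration_s = numeric(),
                     amplitude_uv = numeric(), cycles = integer(),
                     intra_freq_hz = numeric(), symmetry = numeric())
  attr(df, "peaks") <- list()
  class(df) <- c("spindle_table", "data.frame")
  df
}

#' Spindle features
#'
#' Computes the five features of one spindle from the unnormalized
#' band-passed segment covering the event span:
#' \itemize{
#'   \item `duration_s`: first-to-last selected-peak span;
#'   \item `amplitude_uv`: maximal positive minus minimal negative local
#'     extremum (microvolts);
#'   \item `cycles`: number of positive local maxima in the span (all of
#'     them by default, only supra-threshold ones with
#'     `all_extrema = FALSE`, in which case `peak_values` must be given);
#'   \item `intra_freq_hz`: `cycles / duration_s`;
#'   \item `symmetry`: position of the maximal positive peak relative to
#'     the event span, in [0, 1].
#' }
#'
#' @param filtered_segment Band-passed trace between the first and last
#'   selected peak (inclusive).
#' @param peak_times Selected-peak times in seconds (record clock).
#' @param fs Sampling rate in Hz.
#' @param all_extrema Count all positive maxima (default) or selected
#'   ones only.
#' @return List with `amplitude_uv`, `cycles`, `intra_freq_hz`,
#'   `symmetry`, `duration_s`.
#' @export
spindle_features <- function(filtered_segment, peak_times, fs,
                             all_extrema = TRUE) {
  if (!length(filtered_segment))
    stop("spindle_features: empty segment")
  dur <- max(peak_times) - min(peak_times)
  if (dur <= 0) stop("spindle_features: degenerate peak times")
  ext <- local_extrema(filtered_segment)
  # segment endpoints are themselves selected peaks; include them
  ext <- sort(unique(c(1L, ext, length(filtered_segment))))
  v <- filtered_segment[ext]
  pos <- ext[v > 0 & is_local_max(filtered_segment, ext)]
  neg <- ext[v < 0 & !is_local_max(filtered_segment, ext)]
  if (!all_extrema) {
    # selected peaks only: keep positive maxima among the stored peaks
    pk_idx <- round((peak_times - min(peak_times)) * fs) + 1L
    pos <- intersect(pos, pk_idx)
  }
  amp <- (if (length(pos)) max(filtered_segment[pos]) else max(filtered_segment)) -
         (if (length(neg)) min(filtered_segment[neg]) else min(filtered_segment))
  cycles <- max(length(pos), 1L)
  i_max <- if (length(pos)) pos[which.max(filtered_segment[pos])] else
    which.max(filtered_segment)
  sym <- min(max(((i_max - 1) / fs) / dur, 0), 1)
  list(amplitude_uv = amp, cycles = cycles,
       intra_freq_hz = cycles / dur, symmetry = sym, duration_s = dur)
}

# is each index in `idx` a local maximum of x (vs. minimum)?
is_local_max <- function(x, idx) {
  vapply(idx, function(i) {
    left <- if (i > 1) x[i - 1] else x[i + 1]
    right <- if (i < length(x)) x[i + 1] else x[i - 1]
    x[i] >= left && x[i] >= right
  }, logical(1))
}

#' Summarize spindles over a 24-h period
#'
#' Density (count per second of NREM) and feature means over the
#' spindles whose midpoint lies in the given 24-h day of the record.
#'
#' @param spindles A `spindle_table` from [detect_spindles()].
#' @param h The record's [hypnogram()].
#' @param day 24-h period index (1-based; default 1).
#' @return List with `count`, `nrem_s`, `density_per_s` and the feature
#'   means (`NA` when no spindles were detected).
#' @export
spindle_summary <- function(spindles, h, day = 1) {
  stopifnot(inherits(h, "hypnogram"))
  from <- (day - 1) * 86400
  to <- day * 86400
  nrem_s <- state_seconds(h, "NREM", from, to)
  if (nrem_s <= 0)
    stop("spindle_summary: no NREM time in the requested period")
  mid <- (spindles$start_s + spindles$end_s) / 2
  sp <- spindles[mid >= from & mid < to, , drop = FALSE]
  k <- nrow(sp)
  m <- function(x) if (k) mean(x) else NA_real_
  list(count = k, nrem_s = nrem_s, density_per_s = k / nrem_s,
       mean_amplitude_uv = m(sp$amplitude_uv),
       mean_intra_freq_hz = m(sp$intra_freq_hz),
       mean_symmetry = m(sp$symmetry),
       mean_duration_s = m(sp$duration_s))
}

#' Re-check the printed spindle acceptance rules
#'
#' Verifies, from the stored selected-peak times, that every event in a
#' `spindle_table` has more than `min_peaks` peaks, spans more than
#' `min_span_s`, and has every inter-peak gap below `max_gap_s`.
#'
#' @inheritParams detect_spindles
#' @param spindles A `spindle_table`.
#' @return Logical vector, one entry per spindle.
#' @export
check_spindle_rules <- function(spindles, max_gap_s = 0.16, min_peaks = 5,
                                min_span_s = 0.2) {
  pk <- attr(spindles, "peaks")
  vapply(seq_len(nrow(spindles)), function(i) {
    p <- pk[[i]]
    length(p) > min_peaks &&
      (max(p) - min(p)) > min_span_s &&
      all(diff(p) < max_gap_s)
  }, logical(1))
}
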