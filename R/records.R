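# Core containers: synchronized EEG/EMG records and hypnograms.

#' Construct a signal record
#'
#' A synchronized two-channel (EEG + EMG) recording with its sampling
#' rate and clock-time origin. The light phase is 21:00-9:00 and the dark
#' phase 9:00-21:00 (reverse-cycle housing), derived from `t0`.
#'
#' @param eeg,emg Numeric traces in microvolts; equal length.
#' @param fs Sampling rate in Hz (default 500).
#' @param t0 Clock time of the first sample, `"HH:MM"` (default "09:00",
#'   i.e. recordings start at dark onset).
#' @param subject_id Subject identifier.
#' @param day_index Study day (integer).
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(eeg, emg, fs = 500, t0 = "09:00",
                          subject_id = "subject", day_index = 1L) {
  stopifnot(is.numeric(eeg), is.numeric(emg))
  if (length(eeg) != length(emg))
    stop("signal_record: eeg and emg must have equal length")
  if (!is.numeric(fs) || fs <= 0) stop("signal_record: fs must be > 0")
  parse_clock(t0) # validates
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg), fs = fs,
                 t0 = t0, subject_id = as.character(subject_id),
                 day_index = as.integer(day_index)),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("signal_record '%s' day %d: %.1f s at %g Hz, t0 %s\n",
              x$subject_id, x$day_index, length(x$eeg) / x$fs, x$fs, x$t0))
  invisible(x)
}

#' Record duration in seconds
#' @param rec A `signal_record`.
#' @return Duration in seconds.
#' @export
record_duration <- function(rec) length(rec$eeg) / rec$fs

# "HH:MM" -> seconds after midnight
parse_clock <- function(t0) {
  m <- regmatches(t0, regexec("^([0-2]?[0-9]):([0-5][0-9])$", t0))[[1]]
  if (length(m) != 3 || as.integer(m[2]) > 23)
    stop("invalid clock time, expected HH:MM: ", t0)
  as.integer(m[2]) * 3600 + as.integer(m[3]) * 60
}

# phase of a record-time offset (seconds since record start):
# light 21:00-9:00, dark 9:00-21:00
phase_of <- function(t, t0) {
  tod <- (parse_clock(t0) + t) %% 86400
  ifelse(tod >= 9 * 3600 & tod < 21 * 3600, "dark", "light")
}

.sb_states <- c("AWAKE", "NREM", "REM", "UNDETECTABLE")

#' Construct a hypnogram
#'
#' Per-epoch sleep/wake labels over AWAKE, NREM, REM and UNDETECTABLE.
#'
#' @param labels Character vector of per-epoch labels.
#' @param epoch_len_s Epoch length in seconds (default 5).
#' @param t0 Clock time of the first epoch, `"HH:MM"`.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len_s = 5, t0 = "09:00") {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .sb_states)
  if (length(bad))
    stop("hypnogram: unknown label(s): ", paste(bad, collapse = ", "))
  parse_clock(t0)
  structure(list(labels = labels, epoch_len_s = epoch_len_s, t0 = t0),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(factor(x$labels, levels = .sb_states))
  cat(sprintf("hypnogram: %d epochs x %g s (t0 %s)\n",
              length(x$labels), x$epoch_len_s, x$t0))
  print(tb)
  invisible(x)
}

#' Hypnogram duration in seconds
#' @param h A `hypnogram`.
#' @return Total covered time in seconds.
#' @export
hypnogram_duration <- function(h) length(h$labels) * h$epoch_len_s

# seconds spent in `state` inside the window [from_s, to_s)
state_seconds <- function(h, state, from_s = 0, to_s = Inf) {
  starts <- (seq_along(h$labels) - 1) * h$epoch_len_s
  sum(h$labels == state & starts >= from_s & starts < to_s) * h$epoch_len_s
}
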