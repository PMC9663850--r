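# Readers and writers for the formats the pipeline touches: CSV signal
# fixtures with a JSON metadata sidecar, EDF (European Data Format,
# 16-bit), hypnogram CSV, spindle TSV, and the long-format metrics CSV.
# CSV is the canonical fixture format; EDF is for interoperability with
# telemetry exports.

meta_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".meta.json")

#' Write / read a signal record
#'
#' CSV format: columns `time_s`, `eeg_uv`, `emg_uv` at 6 decimal places,
#' with a `<stem>.meta.json` sidecar holding `fs`, `t0`, `subject_id`,
#' `day_index`. EDF format: standard 16-bit EDF with one EEG and one EMG
#' channel (identified on read by case-insensitive "EEG"/"EMG" label
#' substrings), 1-s data records; the trace is truncated to whole
#' seconds and quantized to the channel's physical range.
#'
#' @param rec A [signal_record()].
#' @param path Output file; format inferred from the extension unless
#'   given.
#' @param format `"csv"` or `"edf"`.
#' @return `path`, invisibly (writer); a [signal_record()] (reader).
#' @export
write_signal_record <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "signal_record"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    n <- length(rec$eeg)
    df <- data.frame(time_s = sprintf("%.6f", (0:(n - 1)) / rec$fs),
                     eeg_uv = sprintf("%.6f", rec$eeg),
                     emg_uv = sprintf("%.6f", rec$emg))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(fs = rec$fs, t0 = rec$t0,
                              subject_id = rec$subject_id,
                              day_index = rec$day_index),
                         meta_path(path), auto_unbox = TRUE)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' @rdname write_signal_record
#' @export
read_signal_record <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("read_signal_record: no such file: ", path)
  if (format == "edf") return(read_edf(path))
  df <- utils::read.csv(path)
  need <- c("time_s", "eeg_uv", "emg_uv")
  if (!all(need %in% names(df)))
    stop("read_signal_record: CSV must have columns ",
         paste(need, collapse = ", "))
  mp <- meta_path(path)
  if (!file.exists(mp))
    stop("read_signal_record: missing metadata sidecar ", mp)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  signal_record(df$eeg_uv, df$emg_uv, fs = meta$fs, t0 = meta$t0,
                subject_id = meta$subject_id,
                day_index = meta$day_index %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- EDF ----------------------------------------------------------------

pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf: sampling rate must be an integer number of Hz")
  fs <- as.integer(round(fs))
  nrec <- length(rec$eeg) %/% fs
  if (nrec < 1) stop("write_edf: record shorter than one second")
  chans <- list(EEG = rec$eeg[seq_len(nrec * fs)],
                EMG = rec$emg[seq_len(nrec * fs)])
  # physical range must round-trip through its 8-char header field, so
  # quantize against the value as written
  pm <- vapply(chans, function(x)
    as.numeric(sprintf("%.4g", max(max(abs(x)), 1e-6) * 1.001)), numeric(1))
  t0s <- parse_clock(rec$t0)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(rec$subject_id, 80), pad(sprintf("day %d", rec$day_index), 80),
    pad("01.01.01", 8),
    pad(sprintf("%02d.%02d.00", t0s %/% 3600, (t0s %% 3600) %/% 60), 8),
    pad(256 * (1 + length(chans)), 8), pad("", 44), pad(nrec, 8), pad("1", 8),
    pad(length(chans), 4))
  field <- function(vals, w) paste(vapply(vals, pad, character(1), w = w),
                                   collapse = "")
  hdr <- paste0(hdr,
    field(c("EEG cortical", "EMG trapezius"), 16),
    field(c("", ""), 80), field(c("uV", "uV"), 8),
    field(sprintf("%.4g", -pm), 8), field(sprintf("%.4g", pm), 8),
    field(c("-32768", "-32768"), 8), field(c("32767", "32767"), 8),
    field(c("", ""), 80), field(c(fs, fs), 8), field(c("", ""), 32))
  writeChar(hdr, con, eos = NULL)
  # exact inverse of the reader's affine map over [-pm, pm] x [-32768, 32767]
  dig <- lapply(seq_along(chans), function(i)
    as.integer(pmin(pmax(round((chans[[i]] + pm[i]) / (2 * pm[i]) * 65535
                               - 32768), -32768L), 32767L)))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_along(chans))
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  if (!nzchar(ver) || is.na(suppressWarnings(as.numeric(ver))))
    stop("read_edf: unreadable header")
  subject_id <- rd(80)
  recording <- rd(80)
  rd(8)                                   # start date
  stime <- rd(8)
  rd(8)                                   # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (anyNA(c(nrec, recdur, ns)) || ns < 1)
    stop("read_edf: unreadable header")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  pick <- function(tag) {
    i <- grep(tag, labels, ignore.case = TRUE)
    if (!length(i)) stop("read_edf: no channel labeled like '", tag, "'")
    i[1]
  }
  i_eeg <- pick("EEG"); i_emg <- pick("EMG")
  if (spr[i_eeg] != spr[i_emg])
    stop("read_edf: EEG and EMG sampling rates differ; resampling is not performed")
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(nrec * spr[i])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) != spr[i]) stop("read_edf: truncated data record")
      raw[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  phys <- function(i)
    (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
  hm <- strsplit(stime, ".", fixed = TRUE)[[1]]
  t0 <- if (length(hm) >= 2) sprintf("%02d:%02d", as.integer(hm[1]),
                                     as.integer(hm[2])) else "00:00"
  day <- suppressWarnings(as.integer(sub("^day ", "", recording)))
  signal_record(phys(i_eeg), phys(i_emg), fs = spr[i_eeg] / recdur, t0 = t0,
                subject_id = subject_id,
                day_index = if (is.na(day)) 1L else day)
}

#' EDF quantization step
#'
#' The physical value of one digital unit for each channel of an EDF
#' file written by [write_signal_record()]; round-trip error is bounded
#' by half this step.
#'
#' @param path EDF file.
#' @return Named numeric vector (one entry per channel).
#' @export
edf_quantization_step <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 252, useBytes = TRUE)
  ns <- as.integer(trimws(readChar(con, 4, useBytes = TRUE)))
  fld <- function(w) vapply(seq_len(ns), function(i)
    trimws(readChar(con, w, useBytes = TRUE)), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  stats::setNames((pmax_ - pmin_) / (dmax - dmin), labels)
}

# ---- hypnogram CSV ------------------------------------------------------

#' Write / read a hypnogram CSV
#'
#' Columns `epoch_index`, `start_s`, `label`; labels must be AWAKE,
#' NREM, REM or UNDETECTABLE (anything else is a format error on read).
#' Round trips are lossless.
#'
#' @param h A [hypnogram()].
#' @param path CSV file path.
#' @return `path` invisibly (writer); a [hypnogram()] (reader).
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  n <- length(h$labels)
  df <- data.frame(epoch_index = seq_len(n),
                   start_s = sprintf("%.6f", (seq_len(n) - 1) * h$epoch_len_s),
                   label = h$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(epoch_len_s = h$epoch_len_s, t0 = h$t0),
                       meta_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, colClasses = c(label = "character"))
  bad <- setdiff(unique(df$label), .sb_states)
  if (length(bad))
    stop("read_hypnogram: unknown label(s): ", paste(bad, collapse = ", "))
  mp <- meta_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    hypnogram(df$label, meta$epoch_len_s, meta$t0)
  } else {
    L <- if (nrow(df) > 1) df$start_s[2] - df$start_s[1] else 5
    hypnogram(df$label, L)
  }
}

# ---- spindle TSV --------------------------------------------------------

#' Write a spindle table as TSV
#'
#' One row per spindle, sorted by `start_s`; columns `subject`,
#' `start_s`, `end_s`, `duration_s`, `amplitude_uv`, `cycles`,
#' `intra_freq_hz`, `symmetry` (seconds and microvolts at 6 decimals).
#'
#' @param spindles A `spindle_table` (or compatible data frame).
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_spindle_table <- function(spindles, path) {
  sp <- as.data.frame(spindles)[order(spindles$start_s), , drop = FALSE]
  num <- c("start_s", "end_s", "duration_s", "amplitude_uv",
           "intra_freq_hz", "symmetry")
  for (cc in num) sp[[cc]] <- sprintf("%.6f", sp[[cc]])
  utils::write.table(sp, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spindle_table
#' @export
read_spindle_table <- function(path) {
  df <- utils::read.delim(path)
  class(df) <- c("spindle_table", "data.frame")
  df
}

# ---- metrics CSV --------------------------------------------------------

#' Write a long-format metrics CSV
#'
#' Columns `subject`, `day`, `state`, `metric`, `value`, `rel_units`
#' (logical flag: `TRUE` when the value is baseline-normalized).
#'
#' @param df Data frame with those columns.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(df, path) {
  need <- c("subject", "day", "state", "metric", "value", "rel_units")
  if (!all(need %in% names(df)))
    stop("write_metrics_csv: need columns ", paste(need, collapse = ", "))
  utils::write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
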