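# Multitaper spectrograms and per-epoch band powers.
#
# Band powers drive every downstream staging rule, so the conventions are
# fixed here once: the five canonical bands are half-open [low, high) Hz
# intervals and "band power" is the integral of the one-sided power spectral
# density over the band (microvolt^2), not the mean density.

#' Canonical EEG frequency bands
#'
#' Delta 2-4, theta 5-8, alpha 8-13, beta 16-31 and gamma 32-100 Hz.
#' All bands are half-open `[low, high)` so that the shared 8 Hz edge
#' belongs to alpha and the bands never overlap.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(2, 4), theta = c(5, 8), alpha = c(8, 13),
       beta = c(16, 31), gamma = c(32, 100))
}

#' Multitaper spectrogram parameters
#'
#' Defaults follow the standard sleep-EEG convention: 5-s sliding window
#' advanced by 0.1 s, time-bandwidth product 3 with 5 DPSS tapers, EEG
#' analysed over 0-150 Hz (use `band_limit = c(5, 170)` for EMG).
#'
#' @param window_s Sliding window length in seconds.
#' @param step_s Window step in seconds; must be smaller than `window_s`.
#' @param time_bandwidth DPSS time-bandwidth product.
#' @param n_tapers Number of DPSS tapers averaged (unweighted).
#' @param band_limit Two-element `c(low, high)` Hz; frequencies outside are
#'   dropped from the spectrogram.
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(window_s = 5, step_s = 0.1, time_bandwidth = 3,
                            n_tapers = 5, band_limit = c(0, 150)) {
  stopifnot(is.numeric(window_s), is.numeric(step_s))
  if (!(window_s > step_s && step_s > 0))
    stop("spectral_params: need window_s > step_s > 0")
  if (n_tapers < 1) stop("spectral_params: n_tapers must be >= 1")
  if (length(band_limit) != 2 || band_limit[2] <= band_limit[1])
    stop("spectral_params: band_limit must be c(low, high) with low < high")
  structure(list(window_s = window_s, step_s = step_s,
                 time_bandwidth = time_bandwidth, n_tapers = n_tapers,
                 band_limit = band_limit),
            class = "spectral_params")
}

# cache: DPSS tapers are expensive (dense symmetric eigenproblem)
.sb_dpss_cache <- new.env(parent = emptyenv())

# Discrete prolate spheroidal sequences from the symmetric tridiagonal
# commuting matrix (diagonal ((n-1-2t)/2)^2 cos(2 pi W), off-diagonal
# t(n-t)/2). For windows longer than 1024 samples the sequences are
# computed on a 1024-point grid and spline-interpolated to full length,
# then renormalised to unit energy; the interpolation error is far below
# the statistical noise floor of any spectrogram frame.
dpss_tapers <- function(n, nw = 3, k = 5) {
  stopifnot(n >= 8, k >= 1, nw > 0)
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  hit <- .sb_dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  n0 <- if (n > 1024) 1024L else as.integer(n)
  W <- nw / n0
  t <- 0:(n0 - 1)
  dg <- ((n0 - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  od <- (1:(n0 - 1)) * (n0 - 1:(n0 - 1)) / 2
  A <- matrix(0, n0, n0)
  diag(A) <- dg
  A[cbind(1:(n0 - 1), 2:n0)] <- od
  A[cbind(2:n0, 1:(n0 - 1))] <- od
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  if (n0 < n) {
    grid0 <- seq(0, 1, length.out = n0)
    grid1 <- seq(0, 1, length.out = n)
    V <- apply(V, 2, function(v) stats::spline(grid0, v, xout = grid1)$y)
  }
  # unit energy; fix sign so each taper starts its main lobe positive
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  .sb_dpss_cache[[key]] <- V
  V
}

#' Thomson multitaper spectrogram
#'
#' Sliding-window multitaper power spectral density: each frame is tapered
#' with `n_tapers` DPSS sequences (unit energy, unweighted average across
#' tapers) and the one-sided PSD is returned in signal-units^2 per Hz.
#'
#' @param x Numeric signal (microvolts for EEG/EMG).
#' @param fs Sampling rate in Hz.
#' @param params A [spectral_params()] object.
#' @return An object of class `spectrogram`: list with `times` (frame
#'   centers, s), `freqs` (Hz, clipped to `band_limit`), `power`
#'   (frames x bins matrix), plus the window/step/fs/duration metadata.
#' @export
multitaper_spectrogram <- function(x, fs, params = spectral_params()) {
  stopifnot(is.numeric(x), fs > 0)
  nwin <- round(params$window_s * fs)
  nstep <- round(params$step_s * fs)
  n <- length(x)
  if (n < nwin)
    stop("multitaper_spectrogram: signal shorter than one window")
  tapers <- dpss_tapers(nwin, params$time_bandwidth, params$n_tapers)
  starts <- seq(1L, n - nwin + 1L, by = nstep)
  nf <- length(starts)
  nfreq <- nwin %/% 2 + 1
  freqs_all <- (0:(nfreq - 1)) * fs / nwin
  keep <- which(freqs_all >= params$band_limit[1] &
                  freqs_all <= params$band_limit[2])
  P <- matrix(0, length(keep), nf)
  chunk <- 256L
  for (i0 in seq(1L, nf, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nf)
    # frame matrix nwin x length(idx)
    fm <- matrix(x[outer(0:(nwin - 1L), starts[idx], `+`)], nrow = nwin)
    acc <- matrix(0, length(keep), length(idx))
    for (k in seq_len(ncol(tapers))) {
      X <- stats::mvfft(fm * tapers[, k])[keep, , drop = FALSE]
      acc <- acc + Re(X * Conj(X))
    }
    P[, idx] <- acc
  }
  P <- P / (ncol(tapers) * fs)
  # one-sided: double every bin except DC and (if present) Nyquist
  dbl <- rep(2, length(keep))
  dbl[freqs_all[keep] == 0] <- 1
  if (nwin %% 2 == 0) dbl[freqs_all[keep] == fs / 2] <- 1
  P <- P * dbl
  structure(list(times = (starts - 1 + (nwin - 1) / 2) / fs,
                 freqs = freqs_all[keep],
                 power = t(P),
                 window_s = params$window_s, step_s = params$step_s,
                 fs = fs, df = fs / nwin, duration_s = n / fs),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d frames x %d bins, %g-%g Hz, window %g s step %g s\n",
              length(x$times), length(x$freqs), min(x$freqs), max(x$freqs),
              x$window_s, x$step_s))
  invisible(x)
}

# integral of PSD over [low, high) for every frame
band_integral <- function(spec, low, high) {
  cols <- which(spec$freqs >= low & spec$freqs < high)
  if (!length(cols)) return(rep(0, length(spec$times)))
  rowSums(spec$power[, cols, drop = FALSE]) * spec$df
}

#' Per-epoch band powers
#'
#' Integrates the EEG spectrogram over the five canonical bands (see
#' [eeg_bands()]) and the EMG spectrogram over its full frequency range,
#' then averages over the spectrogram frames whose centers fall inside
#' each non-overlapping epoch (aligned to the record start). Epochs that
#' contain no frame center are reported as `NA` (missing).
#'
#' @param eeg_spec,emg_spec [multitaper_spectrogram()] outputs for the EEG
#'   and EMG channel of the same record. `emg_spec` may be `NULL`, in
#'   which case `emg_power` is `NA` throughout.
#' @param epoch_len_s Epoch length in seconds (default 5).
#' @return A `band_power_table` data frame: `epoch_index` (1-based),
#'   `start_s`, `delta`, `theta`, `alpha`, `beta`, `gamma`, `emg_power`.
#' @export
epoch_band_powers <- function(eeg_spec, emg_spec, epoch_len_s = 5) {
  stopifnot(inherits(eeg_spec, "spectrogram"))
  if (epoch_len_s <= eeg_spec$step_s)
    stop("epoch_band_powers: epoch_len_s must exceed the spectrogram step")
  n_ep <- floor(eeg_spec$duration_s / epoch_len_s)
  if (n_ep < 1) stop("epoch_band_powers: record shorter than one epoch")
  ep_of <- function(times) {
    e <- floor(times / epoch_len_s) + 1L
    e[e < 1L | e > n_ep] <- NA_integer_
    e
  }
  avg_by_epoch <- function(vals, e) {
    out <- rep(NA_real_, n_ep)
    ok <- !is.na(e)
    if (any(ok)) {
      m <- tapply(vals[ok], e[ok], mean)
      out[as.integer(names(m))] <- as.numeric(m)
    }
    out
  }
  e_eeg <- ep_of(eeg_spec$times)
  bands <- eeg_bands()
  bp <- lapply(bands, function(b)
    avg_by_epoch(band_integral(eeg_spec, b[1], b[2]), e_eeg))
  emg <- rep(NA_real_, n_ep)
  if (!is.null(emg_spec)) {
    stopifnot(inherits(emg_spec, "spectrogram"))
    lim <- range(emg_spec$freqs)
    emg <- avg_by_epoch(band_integral(emg_spec, lim[1], lim[2] + emg_spec$df),
                        ep_of(emg_spec$times))
  }
  out <- data.frame(epoch_index = seq_len(n_ep),
                    start_s = (seq_len(n_ep) - 1) * epoch_len_s,
                    delta = bp$delta, theta = bp$theta, alpha = bp$alpha,
                    beta = bp$beta, gamma = bp$gamma, emg_power = emg)
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Robust scale: standard deviation from the median
#'
#' The scale statistic used by every staging threshold:
#' `s_med = sqrt(mean((x - median(x))^2))`.
#'
#' @param x Non-empty numeric vector (`NA`s dropped).
#' @return List with `median` and `s_med`.
#' @export
robust_scale <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("robust_scale: empty input")
  med <- stats::median(x)
  list(median = med, s_med = sqrt(mean((x - med)^2)))
}
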