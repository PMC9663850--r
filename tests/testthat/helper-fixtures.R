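# Shared fixture builders. Everything is generated in code; sizes are
# kept small so the whole suite stays fast.

# band-power table with prescribed per-epoch values (recycled)
make_bp <- function(n, delta = 1, theta = 1, alpha = 1, beta = 1,
                    gamma = 1, emg = 1, epoch_len_s = 5) {
  out <- data.frame(epoch_index = seq_len(n),
                    start_s = (seq_len(n) - 1) * epoch_len_s,
                    delta = rep_len(delta, n), theta = rep_len(theta, n),
                    alpha = rep_len(alpha, n), beta = rep_len(beta, n),
                    gamma = rep_len(gamma, n), emg_power = rep_len(emg, n))
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("band_power_table", "data.frame")
  out
}

# a short simulated record + planted truth (cached per test file run)
sim_fixture <- function(seed = 1, duration_h = 0.5, t0 = "18:00", ...) {
  cfg <- sim_config(duration_h = duration_h, t0 = t0, ...)
  hs <- simulate_hypnogram(cfg, seed)
  ss <- simulate_signals(hs$hypnogram, cfg, seed)
  list(cfg = cfg, hypnogram = hs$hypnogram, record = ss$record,
       truth = ss$truth)
}

# interval-overlap matching between detected and planted event tables
event_overlap <- function(detected, planted) {
  recall <- if (nrow(planted)) mean(vapply(seq_len(nrow(planted)),
    function(i) any(detected$start_s < planted$end_s[i] &
                      detected$end_s > planted$start_s[i]), logical(1)))
    else NA_real_
  precision <- if (nrow(detected)) mean(vapply(seq_len(nrow(detected)),
    function(i) any(planted$start_s < detected$end_s[i] &
                      planted$end_s > detected$start_s[i]), logical(1)))
    else NA_real_
  list(recall = recall, precision = precision)
}

# exhaustive Mann-Whitney oracle: exact two-sided p by enumerating all
# rank assignments (small n only)
mw_exact_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
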