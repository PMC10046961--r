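# Construct a trace with kernel pulses at exact onset times, independently
# of the package's own renderer: plain loop over samples.
make_kernel_trace <- function(onsets, amps, rise = 2, tau = 8, duration = 120,
                              rate_hz = 2, baseline = 100, drift = 0,
                              noise_sd = 0, seed = NULL, window = "baseline") {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * rate_hz)
  tt <- seq(0, by = 1 / rate_hz, length.out = n)
  v <- baseline + drift * tt
  for (k in seq_along(onsets)) {
    t0 <- onsets[k]
    for (i in seq_len(n)) {
      dt <- tt[i] - t0
      if (dt < 0) next
      v[i] <- v[i] + if (dt <= rise) amps[k] * dt / rise else
        amps[k] * exp(-(dt - rise) / tau)
    }
  }
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  new_trace(v, rate_hz, well_id = "H12", window = window)
}

# Exact two-sided rank-sum p-value by full enumeration of all assignments
# of the pooled values to the two groups (oracle; independent of pwilcox).
enumerate_ranksum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(N, m)
  us <- apply(splits, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}
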