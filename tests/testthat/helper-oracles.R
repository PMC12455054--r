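# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately use different primitives than the
# implementation (explicit window means and cumulative sums instead of the
# moving-mean/rle path) so agreement is meaningful.

# Brute-force afterdischarge end: recompute the envelope by explicit window
# means over a search region and scan sample by sample for the first index
# at/after stim_end whose following persistence window stays below
# threshold.
oracle_nad_end <- function(rec, stim_end, base_amp, cfg = nad_config(),
                           search_s = NULL) {
  fs <- rec$sample_rate
  x <- abs(rec$samples)
  n <- length(x)
  k <- max(1L, as.integer(round(cfg$envelope_window * fs)))
  if (k %% 2L == 0L) k <- k + 1L          # same odd-window convention
  h <- (k - 1L) %/% 2L
  i0 <- max(1L, as.integer(round((stim_end - rec$t0) * fs)) + 1L)
  i_hi <- if (is.null(search_s)) n else
    min(n, i0 + as.integer(ceiling(search_s * fs)))
  env <- vapply(seq_len(i_hi), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
  thr <- cfg$threshold_factor * base_amp
  below <- env < thr
  P <- max(1L, as.integer(round(cfg$persistence * fs)))
  cs <- cumsum(c(0L, as.integer(below)))
  for (i in i0:(i_hi - P + 1L)) {
    if (cs[i + P] - cs[i] == P)
      return(rec$t0 + (i - 1L) / fs)
  }
  NA_real_
}

# Brute-force recovery scan: explicit loop over candidate volumes.
oracle_recovery_volume <- function(trace, stim_volume, cfg = recovery_config()) {
  bl <- cfg$baseline_volumes
  thr <- cfg$threshold_fraction * mean(trace[(bl[1] + 1):(bl[2] + 1)])
  P <- cfg$persistence_volumes
  n <- length(trace)
  for (v in (stim_volume + 1):(n - 1)) {      # 0-based candidate volumes
    if (v + P > n) break
    if (all(trace[(v + 1):(v + P)] >= thr)) return(v)
  }
  NA_integer_
}

# Conditioned-style recording built directly from samples (1000 Hz).
make_trace <- function(samples, fs = 1000, t0 = 0) {
  lfp_recording(samples, fs, t0 = t0)
}

# Group timecourse built from a bare mean trace (sd 0).
make_group_tc <- function(mean_trace, tr = 2, stim_volume = 960, n = 2) {
  structure(list(mean = as.numeric(mean_trace),
                 sd = rep(0, length(mean_trace)), n = n, tr = tr,
                 stim_volume = stim_volume, condition = "constructed"),
            class = "group_timecourse")
}
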