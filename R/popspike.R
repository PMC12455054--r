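# Population-spike measurement on single test-pulse sweeps recorded before
# and after the fMRI session: amplitude from the first most positive point
# to the following most negative point, latency from stimulus onset.

#' Measure a population spike in a test-pulse sweep
#'
#' Within the search window after stimulus onset (default 2-10 ms, which
#' skips the stimulus artifact), the spike peak is the first sample
#' attaining the window maximum and the trough is the most negative sample
#' after the peak. Amplitude is peak minus trough voltage; latency is
#' measured from stimulus onset to the chosen landmark (the trough, the
#' conventional population-spike minimum, by default). A flat or monotone
#' window without a peak-then-trough structure yields a no-spike result
#' (amplitude 0, latency NA).
#'
#' @param samples Numeric sweep voltages (mV).
#' @param sample_rate Sampling rate, Hz.
#' @param stim_onset Stimulus onset time (s) on the sweep clock (first
#'   sample is at 0 s).
#' @param search_window Window (s) after onset searched for the spike,
#'   default `c(0.002, 0.010)`.
#' @param latency_landmark `"trough"` (default) or `"peak"`.
#' @return An object of class `pop_spike` with `amplitude` (mV), `latency`
#'   (ms from onset), `peak_time` and `trough_time` (ms from onset).
#' @export
measure_pop_spike <- function(samples, sample_rate, stim_onset = 0,
                              search_window = c(0.002, 0.010),
                              latency_landmark = c("trough", "peak")) {
  latency_landmark <- match.arg(latency_landmark)
  samples <- as.numeric(samples)
  tt <- (seq_along(samples) - 1L) / sample_rate
  lo <- stim_onset + search_window[1L]
  hi <- stim_onset + search_window[2L]
  if (lo < 0 || hi > tt[length(tt)])
    stop("search window extends beyond the sweep", call. = FALSE)
  idx <- which(tt >= lo & tt <= hi)
  w <- samples[idx]
  no_spike <- structure(list(amplitude = 0, latency = NA_real_,
                             peak_time = NA_real_, trough_time = NA_real_),
                        class = "pop_spike")
  if (length(w) < 3L || diff(range(w)) == 0) return(no_spike)
  ipk <- which.max(w)                       # first sample attaining the max
  if (ipk >= length(w)) return(no_spike)    # peak at window end: no trough after
  itr <- ipk + which.min(w[(ipk + 1L):length(w)])
  if (w[ipk] <= w[itr]) return(no_spike)
  pk_ms <- (tt[idx[ipk]] - stim_onset) * 1000
  tr_ms <- (tt[idx[itr]] - stim_onset) * 1000
  structure(list(amplitude = w[ipk] - w[itr],
                 latency = if (latency_landmark == "trough") tr_ms else pk_ms,
                 peak_time = pk_ms, trough_time = tr_ms),
            class = "pop_spike")
}

#' @export
print.pop_spike <- function(x, ...) {
  if (x$amplitude == 0)
    cat("<pop_spike> no spike detected\n")
  else
    cat(sprintf("<pop_spike> amplitude %.2f mV, latency %.2f ms (peak %.2f / trough %.2f ms)\n",
                x$amplitude, x$latency, x$peak_time, x$trough_time))
  invisible(x)
}
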