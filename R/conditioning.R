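# Conditioning of raw in-scanner LFP: artifact blanking, decimation to
# 1000 Hz and zero-phase 0.5-100 Hz band-pass filtering, plus the baseline
# (ongoing-activity) amplitude estimate the afterdischarge detector
# thresholds against.

#' Conditioning parameters for in-scanner LFP
#'
#' @param target_rate Rate after decimation, Hz (default 1000).
#' @param hp_cutoff High-pass cutoff, Hz (default 0.5).
#' @param lp_cutoff Low-pass cutoff, Hz (default 100).
#' @param blank_window_stim Half-width (s) of the blanking window around each
#'   stimulation pulse (default 0.005, i.e. 5 ms each side).
#' @param blank_window_gradient Half-width (s) of the blanking window around
#'   each volume trigger, covering the MR gradient artifact (default 0.010).
#' @param baseline_window Length (s) of the pre-stimulation window over which
#'   ongoing activity is averaged (default 60).
#' @return An object of class `conditioning_config`.
#' @export
conditioning_config <- function(target_rate = 1000, hp_cutoff = 0.5,
                                lp_cutoff = 100,
                                blank_window_stim = 0.005,
                                blank_window_gradient = 0.010,
                                baseline_window = 60) {
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < target_rate / 2))
    stop("need 0 < hp_cutoff < lp_cutoff < target_rate/2", call. = FALSE)
  if (blank_window_stim < 0 || blank_window_gradient < 0 || baseline_window < 0)
    stop("windows must be >= 0", call. = FALSE)
  structure(list(target_rate = target_rate, hp_cutoff = hp_cutoff,
                 lp_cutoff = lp_cutoff,
                 blank_window_stim = blank_window_stim,
                 blank_window_gradient = blank_window_gradient,
                 baseline_window = baseline_window),
            class = "conditioning_config")
}

# Merge overlapping [start, end] intervals (rows of a 2-column matrix).
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Blank stimulation and gradient artifacts by linear interpolation
#'
#' Samples inside a window around every stimulation pulse
#' (+/- `blank_window_stim`) and every volume trigger
#' (+/- `blank_window_gradient`) are replaced by a straight line between the
#' last sample before and the first sample after the window. Overlapping
#' windows are merged first, so no sample is interpolated twice and the
#' operation is idempotent. Windows touching a recording edge are filled
#' with the nearest retained sample.
#'
#' @param rec An [lfp_recording] with event times.
#' @param cfg A [conditioning_config].
#' @return The blanked [lfp_recording]; `$processing$blank_count` holds the
#'   number of replaced samples and `$processing$blank_windows` the merged
#'   time intervals (used later to exclude these samples from baseline
#'   estimation).
#' @export
blank_artifacts <- function(rec, cfg = conditioning_config()) {
  stopifnot(inherits(rec, "lfp_recording"))
  centers <- c(rec$stim_pulses, rec$volume_triggers)
  halfw <- c(rep(cfg$blank_window_stim, length(rec$stim_pulses)),
             rep(cfg$blank_window_gradient, length(rec$volume_triggers)))
  keep <- halfw > 0
  centers <- centers[keep]; halfw <- halfw[keep]
  if (!length(centers)) return(rec)
  iv <- merge_intervals(cbind(centers - halfw, centers + halfw))
  x <- rec$samples
  n <- length(x)
  fs <- rec$sample_rate
  blanked <- 0L
  for (i in seq_len(nrow(iv))) {
    # all samples strictly inside the window are replaced
    lo <- ceiling((iv[i, 1L] - rec$t0) * fs) + 1L   # first sample >= start
    hi <- floor((iv[i, 2L] - rec$t0) * fs) + 1L     # last sample <= end
    lo <- max(lo, 1L); hi <- min(hi, n)
    if (lo > hi) next
    a <- lo - 1L; b <- hi + 1L
    if (a >= 1L && b <= n) {
      x[lo:hi] <- x[a] + (x[b] - x[a]) * (lo:hi - a) / (b - a)
    } else if (a >= 1L) {
      x[lo:hi] <- x[a]
    } else if (b <= n) {
      x[lo:hi] <- x[b]
    }
    blanked <- blanked + (hi - lo + 1L)
  }
  rec$samples <- x
  rec$processing$blanked <- TRUE
  rec$processing$blank_count <- rec$processing$blank_count + blanked
  rec$processing$blank_windows <-
    merge_intervals(rbind(rec$processing$blank_windows, iv))
  rec
}

#' Decimate a recording to a lower sample rate
#'
#' An 8th-order zero-phase Butterworth anti-alias low-pass (cutoff at 80% of
#' the new Nyquist frequency) is applied before keeping every
#' `sample_rate / target_rate`-th sample. Event times are carried over
#' unchanged. The rate ratio must be an integer.
#'
#' @param rec An [lfp_recording].
#' @param target_rate New rate in Hz.
#' @return The decimated [lfp_recording].
#' @export
downsample_lfp <- function(rec, target_rate = 1000) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (rec$sample_rate == target_rate) return(rec)
  factor <- rec$sample_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("sample_rate (", rec$sample_rate,
         ") must be an integer multiple of target_rate (", target_rate, ")",
         call. = FALSE)
  factor <- as.integer(round(factor))
  aa <- signal::butter(8, 0.8 / factor, type = "low")
  y <- filtfilt_padded(aa, rec$samples, pad = 10L * factor)
  rec$samples <- y[seq(1L, length(y), by = factor)]
  rec$sample_rate <- target_rate
  rec
}

#' Zero-phase band-pass filtering of a conditioned trace
#'
#' Applies a 4th-order Butterworth high-pass (`hp_cutoff`) followed by a
#' 4th-order low-pass (`lp_cutoff`), each run forward and backward so the
#' filtering introduces no phase shift (timing of afterdischarge ends and
#' population spikes is not biased). The trace mean is removed first, and
#' antisymmetric edge extension keeps the long high-pass time constant from
#' bleeding transients into the trace. A trace shorter than three high-pass
#' time constants cannot be filtered reliably and is rejected.
#'
#' @param rec An [lfp_recording] at `cfg$target_rate`.
#' @param cfg A [conditioning_config].
#' @return The filtered [lfp_recording] (`$processing$filtered` set; a second
#'   call errors rather than filtering twice).
#' @export
band_filter <- function(rec, cfg = conditioning_config()) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (isTRUE(rec$processing$filtered))
    stop("recording is already band-filtered", call. = FALSE)
  if (abs(rec$sample_rate - cfg$target_rate) > 1e-9)
    stop("recording is at ", rec$sample_rate, " Hz; downsample to ",
         cfg$target_rate, " Hz first", call. = FALSE)
  fs <- rec$sample_rate
  warmup <- 3 / cfg$hp_cutoff
  if (lfp_duration(rec) < warmup)
    stop("trace shorter than filter warm-up (", warmup, " s)", call. = FALSE)
  x <- rec$samples - mean(rec$samples)
  pad <- as.integer(ceiling(warmup * fs))
  hp <- signal::butter(4, cfg$hp_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(4, cfg$lp_cutoff / (fs / 2), type = "low")
  y <- filtfilt_padded(lp, filtfilt_padded(hp, x, pad), pad)
  rec$samples <- y
  rec$processing$filtered <- TRUE
  rec$processing$hp_cutoff <- cfg$hp_cutoff
  rec$processing$lp_cutoff <- cfg$lp_cutoff
  rec
}

#' Full conditioning chain: blank, decimate, band-pass
#'
#' @param rec Raw [lfp_recording] (typically 5000 Hz).
#' @param cfg A [conditioning_config].
#' @param blank Blank artifacts before filtering (default TRUE). Blanking
#'   first keeps gradient/stimulus transients from ringing through the
#'   low-pass; set to FALSE to rely on the 100 Hz low-pass alone.
#' @return Conditioned [lfp_recording] at `cfg$target_rate`.
#' @export
condition_lfp <- function(rec, cfg = conditioning_config(), blank = TRUE) {
  if (blank) rec <- blank_artifacts(rec, cfg)
  rec <- downsample_lfp(rec, cfg$target_rate)
  band_filter(rec, cfg)
}

#' Average ongoing-activity amplitude before stimulation
#'
#' Mean absolute amplitude of the conditioned trace over the
#' `cfg$baseline_window` seconds immediately preceding `stim_onset`.
#' Samples that were replaced during artifact blanking are excluded so the
#' interpolated segments do not bias the estimate downwards.
#'
#' @param rec Conditioned [lfp_recording].
#' @param stim_onset Stimulation onset time (s).
#' @param cfg A [conditioning_config].
#' @return An object of class `baseline_stats` with fields
#'   `mean_abs_amplitude` (mV), `window` (start/end, s) and `n_samples_used`.
#' @export
baseline_amplitude <- function(rec, stim_onset, cfg = conditioning_config()) {
  stopifnot(inherits(rec, "lfp_recording"))
  w0 <- stim_onset - cfg$baseline_window
  if (w0 < rec$t0 - 1e-9)
    stop("baseline window starts before the recording", call. = FALSE)
  tt <- lfp_times(rec)
  use <- tt >= w0 & tt < stim_onset
  bw <- rec$processing$blank_windows
  if (!is.null(bw)) {
    for (i in seq_len(nrow(bw)))
      use <- use & !(tt >= bw[i, 1L] & tt <= bw[i, 2L])
  }
  if (!any(use)) stop("no usable samples in the baseline window", call. = FALSE)
  structure(list(mean_abs_amplitude = mean(abs(rec$samples[use])),
                 window = c(w0, stim_onset),
                 n_samples_used = sum(use)),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> mean |amplitude| %.4g mV over [%.1f, %.1f] s (%d samples)\n",
              x$mean_abs_amplitude, x$window[1L], x$window[2L],
              x$n_samples_used))
  invisible(x)
}
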