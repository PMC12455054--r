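# In-memory containers for electrophysiology and BOLD data.

#' Local field potential recording
#'
#' Single-channel LFP trace with its sample rate and the event times needed
#' by downstream analysis: scanner volume triggers (one per TR) and
#' stimulation pulse times. Event times are in seconds on the same clock as
#' the samples (recording starts at `t0`).
#'
#' @param samples Numeric vector of voltages (mV).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param volume_triggers Times (s) of scanner volume triggers; must be
#'   strictly increasing.
#' @param stim_pulses Times (s) of stimulation pulses.
#' @param meta Named list of free-form labels (animal id, condition, ...).
#'
#' @return An object of class `lfp_recording`.
#' @examples
#' rec <- lfp_recording(rnorm(5000), sample_rate = 5000)
#' lfp_duration(rec)
#' @export
lfp_recording <- function(samples, sample_rate, t0 = 0,
                          volume_triggers = numeric(0),
                          stim_pulses = numeric(0),
                          meta = list()) {
  rec <- structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         t0 = as.numeric(t0),
         volume_triggers = as.numeric(volume_triggers),
         stim_pulses = as.numeric(stim_pulses),
         meta = meta,
         processing = list(blanked = FALSE, blank_windows = NULL,
                           blank_count = 0L, filtered = FALSE)),
    class = "lfp_recording")
  validate_lfp_recording(rec)
}

validate_lfp_recording <- function(rec) {
  if (!is.numeric(rec$sample_rate) || length(rec$sample_rate) != 1L ||
      !is.finite(rec$sample_rate) || rec$sample_rate <= 0)
    stop("sample_rate must be a single positive number", call. = FALSE)
  t_end <- rec$t0 + length(rec$samples) / rec$sample_rate
  ev <- c(rec$volume_triggers, rec$stim_pulses)
  if (length(ev) && (min(ev) < rec$t0 - 1e-9 || max(ev) > t_end + 1e-9))
    stop("event times fall outside the recording [",
         rec$t0, ", ", t_end, "] s", call. = FALSE)
  if (length(rec$volume_triggers) > 1L &&
      any(diff(rec$volume_triggers) <= 0))
    stop("volume_triggers must be strictly increasing", call. = FALSE)
  rec
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d samples @ %g Hz (%.1f s), %d triggers, %d pulses\n",
              length(x$samples), x$sample_rate, lfp_duration(x),
              length(x$volume_triggers), length(x$stim_pulses)))
  if (isTRUE(x$processing$blanked))
    cat(sprintf("  blanked: %d samples\n", x$processing$blank_count))
  if (isTRUE(x$processing$filtered))
    cat(sprintf("  band-filtered: %g-%g Hz\n",
                x$processing$hp_cutoff, x$processing$lp_cutoff))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [lfp_recording].
#' @export
lfp_duration <- function(rec) length(rec$samples) / rec$sample_rate

#' Sample times of a recording
#' @param rec An [lfp_recording].
#' @return Numeric vector of times (s), same length as `rec$samples`.
#' @export
lfp_times <- function(rec) {
  rec$t0 + (seq_along(rec$samples) - 1L) / rec$sample_rate
}

#' BOLD volume-of-interest time series
#'
#' One value per acquired volume (TR apart). The stimulation volume index,
#' when present, is 0-based: volume `k` covers `[k * tr, (k + 1) * tr)`
#' seconds, so "image 900 to 959" at TR 2 s is minutes 30-32.
#'
#' @param values Numeric vector, one signal value per volume.
#' @param tr Repetition time in seconds (> 0).
#' @param stim_volume 0-based index of the volume at which stimulation
#'   starts, or `NULL` for unstimulated sessions.
#' @param meta Named list of labels.
#' @return An object of class `bold_series`.
#' @examples
#' bold_series(rnorm(100, 100), tr = 2)
#' @export
bold_series <- function(values, tr = 2, stim_volume = NULL, meta = list()) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a single positive number", call. = FALSE)
  values <- as.numeric(values)
  if (!is.null(stim_volume)) {
    stim_volume <- as.integer(stim_volume)
    if (stim_volume < 0L || stim_volume >= length(values))
      stop("stim_volume must lie within [0, n_volumes)", call. = FALSE)
  }
  structure(list(values = values, tr = tr,
                 n_volumes = length(values),
                 stim_volume = stim_volume, meta = meta),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d volumes @ TR %g s (%.1f min)%s\n",
              x$n_volumes, x$tr, x$n_volumes * x$tr / 60,
              if (is.null(x$stim_volume)) ""
              else sprintf(", stim at volume %d", x$stim_volume)))
  invisible(x)
}

#' Volume-of-interest mask on a 3D voxel grid
#'
#' @param mask Logical/0-1 3D array, or an integer vector of voxel indices
#'   (1-based, column-major) combined with `dim`.
#' @param dim Grid dimensions when `mask` is an index vector.
#' @param label Optional region label.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, dim = NULL, label = "VOI") {
  if (is.array(mask)) {
    if (length(base::dim(mask)) != 3L)
      stop("mask array must be 3D", call. = FALSE)
    dims <- base::dim(mask)
    idx <- which(mask != 0)
  } else {
    if (is.null(dim) || length(dim) != 3L)
      stop("dim (length 3) required when mask is an index vector", call. = FALSE)
    dims <- as.integer(dim)
    idx <- as.integer(mask)
    if (length(idx) && (min(idx) < 1L || max(idx) > prod(dims)))
      stop("mask indices outside the grid", call. = FALSE)
  }
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  structure(list(indices = idx, dim = dims, label = label),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> '%s': %d voxels on a %s grid\n", x$label,
              length(x$indices), paste(x$dim, collapse = "x")))
  invisible(x)
}
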