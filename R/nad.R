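# Detection and scoring of stimulus-evoked neuronal afterdischarges (nAD).
#
# The end of an afterdischarge is the first time after the stimulation train
# at which the amplitude envelope of the conditioned trace stays below five
# times the average pre-stimulation baseline amplitude for more than one
# second; its intensity is the rectified area under the curve per one-second
# bin.

#' Afterdischarge detector parameters
#'
#' @param threshold_factor Multiple of the baseline amplitude below which
#'   activity counts as ended (default 5).
#' @param persistence Time (s) the envelope must stay below threshold for
#'   the event to be considered over (default 1).
#' @param envelope_window Length (s) of the centered moving-average window
#'   applied to the rectified trace (default 0.1).
#' @param max_search Longest interval (s) after stimulation end that is
#'   searched before the event is censored (default 120).
#' @return An object of class `nad_config`.
#' @export
nad_config <- function(threshold_factor = 5, persistence = 1,
                       envelope_window = 0.1, max_search = 120) {
  if (threshold_factor <= 0 || persistence <= 0 || envelope_window <= 0)
    stop("threshold_factor, persistence and envelope_window must be > 0",
         call. = FALSE)
  structure(list(threshold_factor = threshold_factor,
                 persistence = persistence,
                 envelope_window = envelope_window,
                 max_search = max_search),
            class = "nad_config")
}

#' Amplitude envelope of a conditioned trace
#'
#' Centered moving mean of the rectified signal; the estimator behind the
#' detector's threshold comparison.
#'
#' @param rec Conditioned [lfp_recording].
#' @param window Window length in seconds.
#' @return Numeric vector, same length as `rec$samples`.
#' @export
lfp_envelope <- function(rec, window = 0.1) {
  moving_mean(abs(rec$samples), round(window * rec$sample_rate))
}

#' Detect the end of a neuronal afterdischarge
#'
#' Starting at `stim_end`, finds the earliest time `t` such that the
#' envelope stays below `threshold_factor` times the baseline amplitude for
#' the full persistence window `[t, t + persistence]`. Brief dips below
#' threshold shorter than the persistence window do not terminate the
#' event. If no such time exists within `max_search` seconds the event is
#' censored at `max_search`.
#'
#' @param rec Conditioned [lfp_recording] (1000 Hz, band-filtered).
#' @param stim_end End of the stimulation train (s).
#' @param baseline A `baseline_stats` object from [baseline_amplitude()]
#'   (or a single positive number, the mean absolute baseline amplitude).
#' @param cfg A [nad_config].
#' @return An object of class `nad_event` with fields `stim_end`, `nad_end`,
#'   `duration` (s), `censored`, and empty intensity fields (see
#'   [nad_intensity()]).
#' @export
detect_nad_end <- function(rec, stim_end, baseline, cfg = nad_config()) {
  stopifnot(inherits(rec, "lfp_recording"))
  base_amp <- if (inherits(baseline, "baseline_stats"))
    baseline$mean_abs_amplitude else as.numeric(baseline)
  if (!is.finite(base_amp) || base_amp <= 0)
    stop("baseline amplitude must be > 0 (threshold undefined)", call. = FALSE)
  fs <- rec$sample_rate
  env <- lfp_envelope(rec, cfg$envelope_window)
  thr <- cfg$threshold_factor * base_amp
  below <- env < thr
  i0 <- max(1L, as.integer(round((stim_end - rec$t0) * fs)) + 1L)
  persist_n <- max(1L, as.integer(round(cfg$persistence * fs)))
  hit <- first_sustained(below, i0, persist_n)
  t_hit <- if (is.na(hit)) Inf else rec$t0 + (hit - 1L) / fs
  if (is.finite(t_hit) && t_hit <= stim_end + cfg$max_search + 1e-9) {
    nad_end <- max(t_hit, stim_end)
    censored <- FALSE
  } else {
    nad_end <- stim_end + cfg$max_search
    censored <- TRUE
  }
  structure(list(stim_end = stim_end, nad_end = nad_end,
                 duration = nad_end - stim_end, censored = censored,
                 auc_per_second = NULL, total_auc = NA_real_),
            class = "nad_event")
}

#' @export
print.nad_event <- function(x, ...) {
  cat(sprintf("<nad_event> duration %.2f s%s", x$duration,
              if (x$censored) " (censored)" else ""))
  if (!is.na(x$total_auc))
    cat(sprintf(", total AUC %.3g mV*s over %d bins",
                x$total_auc, length(x$auc_per_second)))
  cat("\n")
  invisible(x)
}

#' Afterdischarge intensity: rectified area under the curve per second
#'
#' For each one-second bin from the stimulation end up to the detected
#' event end, integrates the rectified conditioned trace by the trapezoidal
#' rule; a final partial bin is included pro-rata, so the summed intensity
#' equals the integral over the whole event.
#'
#' @param rec Conditioned [lfp_recording].
#' @param event A `nad_event` from [detect_nad_end()].
#' @return The `nad_event` with `auc_per_second` (mV*s per bin) and
#'   `total_auc` filled in.
#' @export
nad_intensity <- function(rec, event) {
  stopifnot(inherits(rec, "lfp_recording"), inherits(event, "nad_event"))
  tt <- lfp_times(rec)
  ax <- abs(rec$samples)
  dur <- event$duration
  n_bins <- ceiling(dur - 1e-9)
  if (n_bins <= 0) {
    event$auc_per_second <- numeric(0)
    event$total_auc <- 0
    return(event)
  }
  auc <- vapply(seq_len(n_bins) - 1L, function(k) {
    trapz_interval(tt, ax, event$stim_end + k,
                   min(event$stim_end + k + 1, event$nad_end))
  }, numeric(1))
  event$auc_per_second <- auc
  event$total_auc <- sum(auc)
  event
}

#' Summarize a per-animal measure as mean and SD
#'
#' @param values Numeric vector (one value per animal, n >= 2).
#' @param label Optional measure/condition label.
#' @return An object of class `group_summary` with `n`, `mean`, `sd`
#'   (sample SD, n - 1 denominator) and the raw `values`.
#' @export
summarize_group <- function(values, label = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least 2 values to summarize a group", call. = FALSE)
  structure(list(n = length(values), mean = mean(values),
                 sd = stats::sd(values), values = values, label = label),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary>%s n = %d: %.2f +/- %.2f\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n, x$mean, x$sd))
  invisible(x)
}
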