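# Seeded synthetic data emulating the combined experiment: in-scanner LFP
# sessions (gradient artifacts every TR, a 160-pulse 20 Hz train, an
# afterdischarge burst with known duration) and BOLD VOI series (anesthetic
# drift regimes, an optional transient positive response, a sustained
# post-stimulus decline with a known recovery time, spontaneous waves, and
# Gaussian baseline noise). Every generator is deterministic given its seed,
# so ground-truth parameters can be recovered end to end by the analysis
# pipeline.

#' Design of one recording session
#'
#' Defaults reproduce the study protocol: TR 2 s, 3660 volumes (122 min),
#' stimulation at volume 960 (32 min) with 160 bipolar pulses at 20 Hz
#' (an 8 s train), LFP sampled at 5000 Hz.
#'
#' @param anesthetic `"isoflurane"` or `"medetomidine"`.
#' @param acetaminophen Acetaminophen present (default FALSE).
#' @param stimulated Stimulation train delivered (default TRUE).
#' @param tr Repetition time, s.
#' @param n_volumes Number of volumes.
#' @param stim_volume 0-based stimulation volume.
#' @param lfp_rate LFP sampling rate, Hz.
#' @param n_pulses Pulses in the stimulation train.
#' @param pulse_rate Pulse rate, Hz.
#' @param seed Integer seed for all randomness in this session.
#' @return An object of class `session_design`.
#' @export
session_design <- function(anesthetic = c("medetomidine", "isoflurane"),
                           acetaminophen = FALSE, stimulated = TRUE,
                           tr = 2, n_volumes = 3660, stim_volume = 960,
                           lfp_rate = 5000, n_pulses = 160, pulse_rate = 20,
                           seed = 1) {
  anesthetic <- match.arg(anesthetic)
  if (stim_volume < 0 || stim_volume >= n_volumes)
    stop("stim_volume must lie within [0, n_volumes)", call. = FALSE)
  structure(list(anesthetic = anesthetic, acetaminophen = acetaminophen,
                 stimulated = stimulated, tr = tr, n_volumes = n_volumes,
                 stim_volume = as.integer(stim_volume), lfp_rate = lfp_rate,
                 n_pulses = as.integer(n_pulses), pulse_rate = pulse_rate,
                 seed = as.integer(seed)),
            class = "session_design")
}

condition_label <- function(design) {
  paste0(substr(design$anesthetic, 1, 3),
         if (design$acetaminophen) "+acet" else "",
         if (design$stimulated) "+stim" else "")
}

#' Ground truth of a synthetic LFP session
#'
#' `nad_duration` is defined as the time after the end of the train at
#' which the rectified-amplitude envelope crosses five times the baseline
#' amplitude on its way down: the quantity the detector estimates.
#'
#' @param nad_duration Afterdischarge duration, s (0 = no afterdischarge).
#' @param nad_amplitude_factor Plateau envelope as a multiple of the
#'   baseline amplitude (> 5 so the event stays suprathreshold until its
#'   nominal end; default 10).
#' @param baseline_amp Mean absolute amplitude of ongoing activity, mV.
#' @param gradient_amp Peak amplitude of the MR gradient artifact, mV.
#' @param stim_artifact_amp Peak amplitude of a stimulation artifact, mV.
#' @return An object of class `lfp_truth`.
#' @export
lfp_truth <- function(nad_duration = 13, nad_amplitude_factor = 10,
                      baseline_amp = 0.05, gradient_amp = 2,
                      stim_artifact_amp = 5) {
  if (nad_duration < 0) stop("nad_duration must be >= 0", call. = FALSE)
  if (nad_duration > 0 && nad_amplitude_factor <= 5)
    stop("nad_amplitude_factor must exceed the 5x detection threshold",
         call. = FALSE)
  structure(list(nad_duration = nad_duration,
                 nad_amplitude_factor = nad_amplitude_factor,
                 baseline_amp = baseline_amp, gradient_amp = gradient_amp,
                 stim_artifact_amp = stim_artifact_amp),
            class = "lfp_truth")
}

# Band-limited (<=100 Hz) Gaussian background rescaled to a target mean
# absolute amplitude.
band_noise <- function(n, fs, mean_abs = 1) {
  lp <- signal::butter(4, 100 / (fs / 2), type = "low")
  x <- filtfilt_padded(lp, stats::rnorm(n), pad = as.integer(fs / 10))
  x <- x - mean(x)
  x * (mean_abs / mean(abs(x)))
}

# Emulate the standard conditioning chain (decimation to 1000 Hz plus the
# 0.5-100 Hz zero-phase band-pass) on a bare component, so generated
# amplitudes can be calibrated in the domain where detection operates.
# Returns the conditioned samples at 1000 Hz.
cond_emulate <- function(x, fs, target_rate = 1000) {
  factor <- as.integer(round(fs / target_rate))
  if (factor > 1L) {
    aa <- signal::butter(8, 0.8 / factor, type = "low")
    x <- filtfilt_padded(aa, x, pad = 10L * factor)[seq(1L, length(x), by = factor)]
  }
  pad <- as.integer(6 * target_rate)
  hp <- signal::butter(4, 0.5 / (target_rate / 2), type = "high")
  lp <- signal::butter(4, 100 / (target_rate / 2), type = "low")
  filtfilt_padded(lp, filtfilt_padded(hp, x - mean(x), pad), pad)
}

#' Generate a synthetic in-scanner LFP session
#'
#' The trace is ongoing band-limited Gaussian activity with mean absolute
#' amplitude `baseline_amp`, plus a damped-oscillation gradient artifact at
#' every volume trigger, a biphasic stimulation artifact at each of the
#' `n_pulses` pulse times, and - from the end of the train - an
#' afterdischarge: a quasi-rhythmic (about 40 Hz) spike train with a 4 ms
#' biphasic kernel riding on elevated noise, amplitude-modulated so the
#' 100 ms rectified envelope sits at `nad_amplitude_factor` times baseline
#' and then decays linearly over the final stretch, crossing the 5x
#' baseline level exactly `nad_duration` seconds after the train ends.
#'
#' Only a window around the stimulation (default 70 s before the train to
#' 140 s after it) is synthesized; `t0` is set so the train occurs at the
#' protocol time of the full session.
#'
#' @param design A [session_design].
#' @param truth An [lfp_truth].
#' @param pre_s Seconds of recording before the train (>= the baseline
#'   window plus filter warm-up).
#' @param post_s Seconds of recording after the train.
#' @return List with `recording` (an [lfp_recording]) and `truth` (the
#'   input truth plus `train_onset`/`train_end` times in seconds).
#' @export
generate_lfp <- function(design, truth = lfp_truth(), pre_s = 70,
                         post_s = 140) {
  stopifnot(inherits(design, "session_design"), inherits(truth, "lfp_truth"))
  fs <- design$lfp_rate
  train_s <- design$n_pulses / design$pulse_rate
  t0 <- design$stim_volume * design$tr - pre_s
  dur <- pre_s + train_s + post_s
  n <- as.integer(round(dur * fs))
  tt <- t0 + (seq_len(n) - 1L) / fs
  train_onset <- design$stim_volume * design$tr
  train_end <- train_onset + train_s

  with_seed(design$seed, {
    # background calibrated so its conditioned mean |x| equals baseline_amp
    bg <- band_noise(n, fs, 1)
    bg <- bg * (truth$baseline_amp / mean(abs(cond_emulate(bg, fs))))
    x <- bg

    # afterdischarge
    D <- truth$nad_duration
    if (design$stimulated && D > 0) {
      f <- truth$nad_amplitude_factor
      L <- 0.2 * D                              # linear decay segment
      t1 <- D - L * (f - 5) / (f - 1)           # plateau end; 5x crossing at D
      env_of <- function(dt) {
        ifelse(dt < 0, 1,
               ifelse(dt <= t1, f,
                      ifelse(dt <= t1 + L, f - (f - 1) * (dt - t1) / L, 1)))
      }
      dt <- tt - train_end
      active <- dt >= 0 & dt <= t1 + L
      if (any(active)) {
        # quasi-rhythmic spiking: gamma ISIs, mean rate 40 Hz, low jitter;
        # biphasic derivative-of-Gaussian kernel (sigma 4 ms) whose energy
        # sits near 40 Hz, inside the conditioning pass band
        isi <- stats::rgamma(ceiling((t1 + L) * 40 * 2) + 20,
                             shape = 20, rate = 20 * 40)
        spike_t <- cumsum(isi)
        spike_t <- spike_t[spike_t <= t1 + L]
        kern_t <- seq(-0.012, 0.012, by = 1 / fs)
        kern <- -kern_t / 0.004 * exp(-kern_t^2 / (2 * 0.004^2))
        spikes <- numeric(n)
        amp_jit <- stats::runif(length(spike_t), 0.8, 1.2)
        for (j in seq_along(spike_t)) {
          i0 <- as.integer(round((train_end + spike_t[j] - t0 - 0.012) * fs)) + 1L
          ii <- i0:(i0 + length(kern) - 1L)
          keep <- ii >= 1L & ii <= n
          spikes[ii[keep]] <- spikes[ii[keep]] + amp_jit[j] * kern[keep]
        }
        floorn <- band_noise(n, fs, 1)
        u <- spikes / mean(abs(spikes[active])) * 0.6 +
          floorn / mean(abs(floorn[active])) * 0.4
        # shape carrying the envelope profile; the background already
        # contributes one baseline unit to the rectified envelope, hence
        # the independent-components sqrt correction
        comp <- sqrt(pmax(env_of(dt)^2 - 1, 0)) * u
        # calibrate the conditioned plateau envelope to its design value
        cc <- cond_emulate(comp, fs)
        dt_c <- (t0 + (seq_along(cc) - 1L) / 1000) - train_end
        plateau <- dt_c >= min(0.2, t1 / 4) & dt_c <= t1 - min(0.2, t1 / 4)
        scale <- truth$baseline_amp * sqrt(f^2 - 1) / mean(abs(cc[plateau]))
        x <- x + scale * comp
      }
    }

    # gradient artifact at every volume trigger: damped 300 Hz oscillation
    triggers <- seq(t0 + 0.5, t0 + dur - 0.1, by = design$tr)
    ga_t <- seq(0, 0.01, by = 1 / fs)
    ga <- truth$gradient_amp * exp(-ga_t / 0.003) * sin(2 * pi * 300 * ga_t)
    for (tg in triggers) {
      i0 <- as.integer(round((tg - t0) * fs)) + 1L
      ii <- i0:(i0 + length(ga) - 1L)
      keep <- ii >= 1L & ii <= n
      x[ii[keep]] <- x[ii[keep]] + ga[keep]
    }

    # biphasic stimulation artifacts at the pulse times
    pulses <- if (design$stimulated)
      train_onset + (seq_len(design$n_pulses) - 1L) / design$pulse_rate
    else numeric(0)
    if (length(pulses)) {
      sa_t <- seq(0, 0.001, by = 1 / fs)
      sa <- truth$stim_artifact_amp * sin(2 * pi * sa_t / 0.001)
      for (tp in pulses) {
        i0 <- as.integer(round((tp - t0) * fs)) + 1L
        ii <- i0:(i0 + length(sa) - 1L)
        keep <- ii >= 1L & ii <= n
        x[ii[keep]] <- x[ii[keep]] + sa[keep]
      }
    }

    rec <- lfp_recording(x, fs, t0 = t0, volume_triggers = triggers,
                         stim_pulses = pulses,
                         meta = list(condition = condition_label(design),
                                     seed = design$seed))
    truth$train_onset <- train_onset
    truth$train_end <- train_end
    list(recording = rec, truth = truth)
  })
}

#' Ground truth of a synthetic BOLD session
#'
#' @param drift `"auto"` (drift regime chosen from the session's anesthetic
#'   and acetaminophen state) or `"none"`.
#' @param transient_amp Amplitude (%) of the transient positive response at
#'   stimulation; emitted only under medetomidine (default 1.5).
#' @param transient_duration Duration (s) of the transient (default 60).
#' @param decline_depth Depth (%) of the immediate post-stimulus decline
#'   (default 3).
#' @param recovery_minutes Minutes after stimulation at which the
#'   stimulus-locked component re-crosses 98% of baseline; `NA` for a
#'   censored (never recovering) decline.
#' @param noise_sd SD (%) of Gaussian volume-to-volume noise (default 0.2).
#' @param wave_rate Spontaneous-wave rate per hour; emitted only under
#'   medetomidine (default 3).
#' @param wave_amp Wave amplitude (%), default 1.
#' @param wave_width Wave Gaussian width (s), default 20.
#' @return An object of class `bold_truth`.
#' @export
bold_truth <- function(drift = c("auto", "none"), transient_amp = 1.5,
                       transient_duration = 60, decline_depth = 3,
                       recovery_minutes = NA_real_, noise_sd = 0.2,
                       wave_rate = 3, wave_amp = 1, wave_width = 20) {
  drift <- match.arg(drift)
  if (!is.na(noise_sd) && noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(drift = drift, transient_amp = transient_amp,
                 transient_duration = transient_duration,
                 decline_depth = decline_depth,
                 recovery_minutes = recovery_minutes,
                 noise_sd = noise_sd, wave_rate = wave_rate,
                 wave_amp = wave_amp, wave_width = wave_width),
            class = "bold_truth")
}

# Intrinsic anesthetic drift (percent) at time t_min (minutes).
# Shapes are the simplest curves consistent with the reported group levels:
# isoflurane rises to ~+1.6% in the first hour then settles at +1.39%;
# with acetaminophen it stays near baseline for ~60 min before rising.
# Medetomidine is flat for 30 min then declines to -4.93% by 122 min;
# with acetaminophen the decline starts immediately (-4.01% by 60 min).
drift_percent <- function(t_min, anesthetic, acetaminophen) {
  if (anesthetic == "isoflurane") {
    if (!acetaminophen) {
      peak <- 1.62 * (1 - exp(-60 / 12))
      ifelse(t_min <= 60, 1.62 * (1 - exp(-t_min / 12)),
             peak + (1.39 - peak) * (t_min - 60) / 62)
    } else {
      ifelse(t_min <= 60, 0.14 * (1 - exp(-t_min / 10)),
             0.14 + (1.68 - 0.14) * (t_min - 60) / 62)
    }
  } else {
    if (!acetaminophen) {
      ifelse(t_min <= 30, 0, -4.93 * (t_min - 30) / 92)
    } else {
      ifelse(t_min <= 60, -4.01 * t_min / 60,
             -4.01 - 0.99 * (t_min - 60) / 62)
    }
  }
}

#' Generate a synthetic BOLD VOI series
#'
#' Builds `100 + drift + stimulus response + waves + noise` per volume.
#' The stimulus-locked component is an immediate step decline of
#' `decline_depth` percent followed by a linear return laid out so that it
#' re-crosses the 98%-of-baseline level exactly `recovery_minutes` minutes
#' after stimulation (or never, when censored); under medetomidine a
#' transient positive half-sine precedes the decline and smooth random
#' "spontaneous BOLD waves" are superimposed.
#'
#' @param design A [session_design].
#' @param truth A [bold_truth].
#' @return List with `series` (a [bold_series]) and `truth`.
#' @export
generate_bold <- function(design, truth = bold_truth()) {
  stopifnot(inherits(design, "session_design"), inherits(truth, "bold_truth"))
  k <- seq_len(design$n_volumes) - 1L     # 0-based volume index
  t_min <- k * design$tr / 60
  with_seed(child_seed(design$seed, 2L), {
    v <- rep(100, design$n_volumes)
    if (truth$drift == "auto")
      v <- v + drift_percent(t_min, design$anesthetic, design$acetaminophen)
    if (design$stimulated) {
      dt_min <- t_min - design$stim_volume * design$tr / 60
      depth <- truth$decline_depth
      shortfall <- 2   # percent below baseline at the 98% criterion
      if (is.na(truth$recovery_minutes) || depth <= shortfall) {
        dec <- ifelse(dt_min >= 0, -depth, 0)
      } else {
        t_full <- truth$recovery_minutes * depth / (depth - shortfall)
        dec <- ifelse(dt_min >= 0, pmin(-depth + depth * dt_min / t_full, 0), 0)
      }
      v <- v + dec
      if (design$anesthetic == "medetomidine" && truth$transient_amp > 0) {
        dt_s <- dt_min * 60
        tp <- ifelse(dt_s >= 0 & dt_s <= truth$transient_duration,
                     truth$transient_amp *
                       sin(pi * dt_s / truth$transient_duration), 0)
        v <- v + tp
      }
    }
    if (design$anesthetic == "medetomidine" && truth$wave_rate > 0) {
      dur_h <- design$n_volumes * design$tr / 3600
      n_waves <- stats::rpois(1L, truth$wave_rate * dur_h)
      if (n_waves > 0) {
        centers <- stats::runif(n_waves, 0, max(t_min))
        amps <- stats::rnorm(n_waves, truth$wave_amp, 0.3 * truth$wave_amp)
        w_min <- truth$wave_width / 60
        for (j in seq_len(n_waves))
          v <- v + amps[j] * exp(-(t_min - centers[j])^2 / (2 * w_min^2))
      }
    }
    if (truth$noise_sd > 0)
      v <- v + stats::rnorm(design$n_volumes, 0, truth$noise_sd)
    series <- bold_series(v, tr = design$tr,
                          stim_volume = if (design$stimulated)
                            design$stim_volume else NULL,
                          meta = list(condition = condition_label(design),
                                      seed = design$seed))
    list(series = series, truth = truth)
  })
}

# Afterdischarge regimes per condition: duration mean/SD (s) of the groups
# the generator emulates, and stimulus-locked BOLD recovery defaults.
nad_regimes <- function() {
  data.frame(
    anesthetic = c("isoflurane", "isoflurane", "medetomidine", "medetomidine"),
    acetaminophen = c(FALSE, TRUE, FALSE, TRUE),
    duration_mean = c(13.01, 11.64, 13.25, 13.66),
    duration_sd = c(4.42, 1.80, 1.85, 1.87),
    recovery_minutes = c(NA, 70, 41, NA),
    stringsAsFactors = FALSE)
}

#' Generate a seeded cohort of synthetic sessions
#'
#' Draws per-animal afterdischarge durations from the condition's regime
#' (normal, truncated above 2 s), expands the cohort seed into independent
#' per-animal seeds, and generates an LFP session (stimulated conditions
#' only) and a BOLD session per animal, together with a ground-truth table.
#'
#' @param design A [session_design] (the condition template).
#' @param n Animals (default 5).
#' @param seed Cohort seed (defaults to `design$seed`).
#' @param lfp Generate LFP sessions (default: only when stimulated).
#' @param bold_noise_sd Noise SD passed to the BOLD truth (default 0.2).
#' @param lfp_post_s Post-train LFP window (s), default 60.
#' @return List with `animals` (list of per-animal lists: `design`, `lfp`,
#'   `bold`) and `truth` (data frame, one row per animal).
#' @export
generate_cohort <- function(design, n = 5, seed = design$seed,
                            lfp = design$stimulated, bold_noise_sd = 0.2,
                            lfp_post_s = 60) {
  reg <- nad_regimes()
  row <- reg[reg$anesthetic == design$anesthetic &
               reg$acetaminophen == design$acetaminophen, ]
  durations <- with_seed(child_seed(seed, 1L), {
    d <- stats::rnorm(n, row$duration_mean, row$duration_sd)
    while (any(d <= 2))
      d[d <= 2] <- stats::rnorm(sum(d <= 2), row$duration_mean, row$duration_sd)
    d
  })
  animals <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    des_i <- design
    des_i$seed <- as.integer(child_seed(seed, 100L + i))
    lfp_i <- NULL
    if (lfp) {
      lt <- lfp_truth(nad_duration = durations[i])
      lfp_i <- generate_lfp(des_i, lt, post_s = lfp_post_s)
    }
    bt <- bold_truth(noise_sd = bold_noise_sd,
                     recovery_minutes = row$recovery_minutes)
    bold_i <- generate_bold(des_i, bt)
    animals[[i]] <- list(design = des_i, lfp = lfp_i, bold = bold_i)
    truth_rows[[i]] <- data.frame(
      animal = i, condition = condition_label(design), seed = des_i$seed,
      nad_duration = durations[i],
      recovery_minutes = row$recovery_minutes,
      stringsAsFactors = FALSE)
  }
  list(animals = animals, truth = do.call(rbind, truth_rows))
}
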