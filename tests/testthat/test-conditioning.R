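test_that("artifact blanking interpolates event windows and is idempotent", {
  fs <- 5000
  x <- rep(0, fs * 2)
  rec0 <- lfp_recording(x, fs, volume_triggers = 1.0)
  cfg <- conditioning_config()

  # no events -> identical output
  rec_none <- lfp_recording(rnorm(fs), fs)
  expect_identical(blank_artifacts(rec_none, cfg)$samples, rec_none$samples)

  # impulse exactly at a trigger is removed, neighbors untouched
  x[round(1.0 * fs) + 1] <- 100
  rec <- lfp_recording(x, fs, volume_triggers = 1.0)
  bl <- blank_artifacts(rec, cfg)
  expect_equal(max(abs(bl$samples)), 0)
  expect_gt(bl$processing$blank_count, 0)

  # idempotence: blanking an already blanked trace changes nothing
  bl2 <- blank_artifacts(bl, cfg)
  expect_identical(bl2$samples, bl$samples)

  # interpolation is linear between window edges
  ramp <- seq_len(fs) / fs
  rec_r <- lfp_recording(ramp, fs, stim_pulses = 0.5)
  rec_r$samples[round(0.5 * fs) + 1] <- 50
  bl_r <- blank_artifacts(rec_r, cfg)
  expect_equal(bl_r$samples, ramp, tolerance = 1e-12)

  # all 160 stimulation artifacts fall inside blank windows
  g <- generate_lfp(session_design(seed = 4), lfp_truth(nad_duration = 0),
                    pre_s = 70, post_s = 10)
  bl_s <- blank_artifacts(g$recording, cfg)
  tt <- lfp_times(bl_s)
  in_pulse <- rowSums(outer(tt, bl_s$stim_pulses,
                            function(a, b) abs(a - b) <= 0.004)) > 0
  base_level <- max(abs(bl_s$samples[tt < bl_s$stim_pulses[1] - 1 & tt >
                                       bl_s$stim_pulses[1] - 11]))
  expect_lte(max(abs(bl_s$samples[in_pulse])), base_level)
})

test_that("decimation preserves duration, events and passband RMS", {
  fs <- 5000
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- lfp_recording(sin(2 * pi * 10 * tt), fs, volume_triggers = c(2, 4))
  dn <- downsample_lfp(rec, 1000)
  expect_length(dn$samples, 10000L)
  expect_identical(dn$volume_triggers, rec$volume_triggers)
  expect_equal(sqrt(mean(dn$samples^2)), 1 / sqrt(2), tolerance = 0.01)

  # already at target rate: unchanged
  expect_identical(downsample_lfp(dn, 1000), dn)
  # non-integer factor rejected
  expect_error(downsample_lfp(rec, 1500), "integer")
})

test_that("band-pass filter rejects DC, keeps the passband, kills the stopband", {
  fs <- 1000
  cfg <- conditioning_config()
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)

  const <- band_filter(make_trace(rep(5, length(tt))), cfg)
  expect_lt(abs(mean(const$samples)), 1e-6)
  expect_lt(max(abs(const$samples)), 1e-6)

  s10 <- band_filter(make_trace(sin(2 * pi * 10 * tt)), cfg)
  mid <- seq(5 * fs, 25 * fs)
  expect_equal(max(abs(s10$samples[mid])), 1, tolerance = 0.02)

  s200 <- band_filter(make_trace(sin(2 * pi * 200 * tt)), cfg)
  expect_lt(max(abs(s200$samples[mid])), 0.1)

  # linearity
  set.seed(5)
  x <- rnorm(length(tt))
  f1 <- band_filter(make_trace(x), cfg)$samples
  f3 <- band_filter(make_trace(3 * x), cfg)$samples
  expect_lt(max(abs(f3 - 3 * f1)), 1e-4)

  # processed flag prevents double filtering; short traces rejected
  expect_error(band_filter(s10, cfg), "already")
  expect_error(band_filter(make_trace(rnorm(fs * 2)), cfg), "warm-up")
  # wrong rate rejected
  expect_error(band_filter(lfp_recording(rnorm(10000), 5000), cfg), "Hz")
})

test_that("baseline amplitude is the rectified mean, excluding blanked spans", {
  fs <- 1000
  cfg <- conditioning_config(baseline_window = 10)

  expect_equal(baseline_amplitude(make_trace(rep(0, 20 * fs)), 15,
                                  cfg)$mean_abs_amplitude, 0)

  sq <- rep(c(1, -1), length.out = 20 * fs)
  expect_equal(baseline_amplitude(make_trace(sq), 15, cfg)$mean_abs_amplitude, 1)

  # Monte-Carlo: |N(0, s)| has mean s * sqrt(2/pi)
  set.seed(6)
  s <- 0.3
  noise <- rnorm(60 * fs, 0, s)
  got <- baseline_amplitude(make_trace(noise), 60,
                            conditioning_config(baseline_window = 60))
  expect_equal(got$mean_abs_amplitude, s * sqrt(2 / pi), tolerance = 0.02)

  # sign-flip invariance
  got2 <- baseline_amplitude(make_trace(-noise), 60,
                             conditioning_config(baseline_window = 60))
  expect_identical(got2$mean_abs_amplitude, got$mean_abs_amplitude)

  # blanked samples are excluded from the mean
  rec <- lfp_recording(c(rep(1, 10 * fs), rep(9, 10 * fs)), fs,
                       stim_pulses = 15)
  rec <- blank_artifacts(rec, conditioning_config(blank_window_stim = 2.5))
  got3 <- baseline_amplitude(rec, 20, cfg)
  expect_equal(got3$mean_abs_amplitude, 9)  # window [10,20), blank [12.5,17.5]
  expect_lt(got3$n_samples_used, 10 * fs)

  # window before the recording start errors
  expect_error(baseline_amplitude(make_trace(rnorm(fs * 5)), 2, cfg),
               "before")
})
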