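test_that("generators are byte-deterministic under a fixed seed", {
  des <- session_design("medetomidine", seed = 17)
  g1 <- generate_lfp(des, lfp_truth(nad_duration = 4), pre_s = 70, post_s = 15)
  g2 <- generate_lfp(des, lfp_truth(nad_duration = 4), pre_s = 70, post_s = 15)
  expect_identical(g1$recording$samples, g2$recording$samples)
  expect_identical(g1$recording$stim_pulses, g2$recording$stim_pulses)

  b1 <- generate_bold(des); b2 <- generate_bold(des)
  expect_identical(b1$series$values, b2$series$values)

  # generation does not disturb the caller's RNG stream
  set.seed(99); r1 <- rnorm(1)
  set.seed(99); invisible(generate_bold(des)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("afterdischarge truth round-trips through the detector", {
  # no afterdischarge: the detector reports zero duration
  des0 <- session_design("isoflurane", seed = 18)
  g0 <- generate_lfp(des0, lfp_truth(nad_duration = 0), post_s = 20)
  r0 <- analyze_lfp_session(g0$recording, g0$truth$train_onset,
                            g0$truth$train_end)
  expect_equal(r0$event$duration, 0, tolerance = 0.3)

  # 10 s truth detected within 0.2 s
  des <- session_design("medetomidine", seed = 19)
  g <- generate_lfp(des, lfp_truth(nad_duration = 10), post_s = 30)
  r <- analyze_lfp_session(g$recording, g$truth$train_onset, g$truth$train_end)
  expect_equal(r$event$duration, 10, tolerance = 0.2)
  expect_false(r$event$censored)

  # plateau factor at or below the detection threshold is rejected
  expect_error(lfp_truth(nad_duration = 5, nad_amplitude_factor = 4),
               "threshold")
})

test_that("BOLD generator reproduces its drift and stimulus truths", {
  # isoflurane drift, noiseless: rises and settles near +1.4%
  iso <- generate_bold(session_design("isoflurane", stimulated = FALSE,
                                      seed = 20),
                       bold_truth(noise_sd = 0))
  v <- iso$series$values
  expect_equal(v[length(v)], 101.39, tolerance = 0.05)
  expect_gt(max(v), 101.5)

  # medetomidine declines late; with acetaminophen it declines immediately
  med <- generate_bold(session_design("medetomidine", stimulated = FALSE,
                                      seed = 20),
                       bold_truth(noise_sd = 0, wave_rate = 0))
  vm <- med$series$values
  expect_equal(vm[900], 100, tolerance = 1e-9)   # flat first 30 min
  expect_equal(vm[length(vm)], 95.07, tolerance = 0.05)
  med_a <- generate_bold(session_design("medetomidine", acetaminophen = TRUE,
                                        stimulated = FALSE, seed = 20),
                         bold_truth(noise_sd = 0, wave_rate = 0))
  expect_equal(med_a$series$values[1800], 100 - 4.01, tolerance = 0.05)

  # grand mean stays near 100 when drift is disabled (unstimulated, noisy)
  flat <- generate_bold(session_design("medetomidine", stimulated = FALSE,
                                       seed = 21),
                        bold_truth(drift = "none", wave_rate = 0))
  expect_lt(abs(mean(flat$series$values) - 100), 0.5)

  # recovery truth closure on the noiseless stimulus-locked component
  for (r in c(41, 85)) {
    g <- generate_bold(session_design("isoflurane", seed = 22),
                       bold_truth(drift = "none", noise_sd = 0,
                                  recovery_minutes = r))
    rr <- recovery_time(make_group_tc(g$series$values))
    expect_true(rr$recovered)
    expect_equal(rr$recovery_minutes, r, tolerance = 0.1)
  }
  cen <- generate_bold(session_design("isoflurane", seed = 22),
                       bold_truth(drift = "none", noise_sd = 0,
                                  recovery_minutes = NA))
  expect_false(recovery_time(make_group_tc(cen$series$values))$recovered)
})

test_that("cohorts expand one seed into reproducible per-animal sessions", {
  des <- session_design("isoflurane", acetaminophen = TRUE, seed = 23,
                        n_volumes = 600, stim_volume = 300)
  co1 <- generate_cohort(des, n = 3, lfp = FALSE)
  co2 <- generate_cohort(des, n = 3, lfp = FALSE)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$animals[[2]]$bold$series$values,
                   co2$animals[[2]]$bold$series$values)
  expect_equal(nrow(co1$truth), 3L)
  # per-animal seeds differ, hence series differ
  expect_false(identical(co1$animals[[1]]$bold$series$values,
                         co1$animals[[2]]$bold$series$values))
  # durations drawn from the condition regime, truncated above 2 s
  expect_true(all(co1$truth$nad_duration > 2))
})
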