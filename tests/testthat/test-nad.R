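# Detector unit tests on constructed traces where the envelope is known in
# closed form; agreement with the brute-force scan oracle is asserted
# throughout.

base_stats <- function(amp) {
  structure(list(mean_abs_amplitude = amp, window = c(0, 60),
                 n_samples_used = 60000L), class = "baseline_stats")
}

# square-wave trace whose 100 ms rectified envelope equals `level` over
# the given spans (list of c(start, end, level))
envelope_trace <- function(total_s, spans, fs = 1000) {
  x <- rep(0, total_s * fs)
  tt <- (seq_along(x) - 1) / fs
  for (sp in spans) {
    sel <- tt >= sp[1] & tt < sp[2]
    x[sel] <- sp[3] * rep(c(1, -1), length.out = sum(sel))
  }
  make_trace(x, fs)
}

test_that("afterdischarge end detection matches construction and oracle", {
  cfg <- nad_config()
  b <- base_stats(1)

  # silent trace: event over immediately
  silent <- envelope_trace(30, list(c(0, 30, 0.5)))
  ev <- detect_nad_end(silent, 10, b, cfg)
  expect_equal(ev$duration, 0)
  expect_false(ev$censored)

  # envelope 10x baseline for exactly 10 s after stim_end, then baseline
  tr <- envelope_trace(40, list(c(0, 20, 10), c(20, 40, 0.5)))
  ev10 <- detect_nad_end(tr, 10, b, cfg)
  expect_equal(ev10$duration, 10, tolerance = cfg$envelope_window)
  expect_equal(ev10$nad_end,
               oracle_nad_end(tr, 10, 1, cfg, search_s = 15))

  # a 0.5 s dip below threshold does not terminate the event
  dip <- envelope_trace(40, list(c(0, 22, 10), c(22, 22.5, 0.5),
                                 c(22.5, 30, 10), c(30, 40, 0.5)))
  ev_dip <- detect_nad_end(dip, 10, b, cfg)
  expect_equal(ev_dip$duration, 20, tolerance = cfg$envelope_window)
  expect_equal(ev_dip$nad_end, oracle_nad_end(dip, 10, 1, cfg, search_s = 25))

  # activity that never subsides within max_search is censored
  loud <- envelope_trace(30, list(c(0, 30, 10)))
  ev_c <- detect_nad_end(loud, 5, b, nad_config(max_search = 20))
  expect_true(ev_c$censored)
  expect_equal(ev_c$duration, 20)

  # zero baseline leaves the threshold undefined
  expect_error(detect_nad_end(tr, 10, base_stats(0), cfg), "baseline")
})

test_that("raising the threshold never lengthens the detected event", {
  set.seed(8)
  tr <- envelope_trace(40, list(c(0, 15, 8), c(15, 18, 4), c(18, 40, 0.5)))
  durs <- vapply(c(2, 3, 5, 6, 9), function(k)
    detect_nad_end(tr, 10, base_stats(1),
                   nad_config(threshold_factor = k))$duration, numeric(1))
  expect_true(all(diff(durs) <= 1e-12))
})

test_that("intensity integrates the rectified trace per second, pro-rata", {
  fs <- 1000
  ev <- structure(list(stim_end = 10, nad_end = 13, duration = 3,
                       censored = FALSE, auc_per_second = NULL,
                       total_auc = NA_real_), class = "nad_event")

  zero <- make_trace(rep(0, 20 * fs))
  expect_equal(nad_intensity(zero, ev)$auc_per_second, rep(0, 3))

  # |x| == 1 mV for the whole event: one mV*s per bin
  ones <- make_trace(rep(c(1, -1), length.out = 20 * fs))
  got <- nad_intensity(ones, ev)
  expect_equal(got$auc_per_second, rep(1, 3), tolerance = 1e-3)
  expect_equal(got$total_auc, sum(got$auc_per_second))

  # doubling the amplitude doubles every bin exactly
  twos <- make_trace(2 * ones$samples)
  expect_equal(nad_intensity(twos, ev)$auc_per_second,
               2 * got$auc_per_second)

  # a final partial bin is counted pro-rata
  ev25 <- ev; ev25$nad_end <- 12.5; ev25$duration <- 2.5
  got25 <- nad_intensity(ones, ev25)
  expect_length(got25$auc_per_second, 3L)
  expect_equal(got25$auc_per_second[3], 0.5, tolerance = 1e-3)

  # zero-duration event has no bins
  ev0 <- ev; ev0$nad_end <- 10; ev0$duration <- 0
  expect_identical(nad_intensity(ones, ev0)$total_auc, 0)
})

test_that("group summaries are plain mean and sample SD", {
  s <- summarize_group(c(13.25, 13.25))
  expect_equal(s$mean, 13.25)
  expect_equal(s$sd, 0)
  s2 <- summarize_group(c(1, 2, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, 1)
  expect_error(summarize_group(5), "at least 2")
})
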