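test_that("normalization sets the grand mean to exactly 100", {
  expect_equal(normalize_bold(bold_series(rep(7, 50)))$values, rep(100, 50))
  expect_equal(normalize_bold(bold_series(c(1, 2, 3)))$values, c(50, 100, 150))

  set.seed(12)
  s <- bold_series(rnorm(200, 50, 3))
  n1 <- normalize_bold(s)
  expect_lt(abs(mean(n1$values) - 100) / 100, 1e-9)

  # scale invariance
  s2 <- s; s2$values <- 4.2 * s$values
  expect_equal(normalize_bold(s2)$values, n1$values)

  expect_error(normalize_bold(bold_series(c(-1, -2, -3))), "positive")
})

test_that("group time courses are per-volume mean and sample SD", {
  a <- bold_series(rep(98, 10)); b <- bold_series(rep(102, 10))
  tc <- group_timecourse(list(a, b))
  expect_equal(tc$mean, rep(100, 10))
  expect_equal(tc$sd, rep(sd(c(98, 102)), 10))  # 2*sqrt(2)/sqrt(2) = 2.828...

  tc_same <- group_timecourse(list(a, a))
  expect_equal(tc_same$sd, rep(0, 10))

  expect_error(group_timecourse(list(a, bold_series(rep(1, 5)))), "length")
})

test_that("pointwise testing flags exactly the planted difference", {
  set.seed(13)
  nvol <- 600
  A <- matrix(rnorm(5 * nvol, 100, 0.01), 5)
  B <- matrix(rnorm(5 * nvol, 100, 0.01), 5)
  B[, 101:200] <- B[, 101:200] + 10   # 0-based volumes 100..199

  pw <- pointwise_difference_test(A, B, alpha = 0.01)
  expect_identical(pw$significant_volumes, 100:199)

  # oracle: per-volume stats::t.test with pooled variance
  p_oracle <- vapply(seq_len(nvol), function(j)
    t.test(A[, j], B[, j], var.equal = TRUE)$p.value, numeric(1))
  expect_equal(pw$p, p_oracle, tolerance = 1e-12)

  # symmetric in the group order; invariant to a common additive shift
  pw_sw <- pointwise_difference_test(B, A, alpha = 0.01)
  expect_identical(pw_sw$mask, pw$mask)
  pw_sh <- pointwise_difference_test(A + 5, B + 5, alpha = 0.01)
  expect_equal(pw_sh$p, pw$p, tolerance = 1e-9)

  # identical groups: empty mask; zero variance handled as p = 1
  pw0 <- pointwise_difference_test(A, A)
  expect_identical(sum(pw0$mask), 0L)
  C <- matrix(1, 3, 4)
  pwc <- pointwise_difference_test(C, C)
  expect_equal(pwc$p, rep(1, 4))
  expect_identical(pwc$degenerate, 4L)

  # paired variant agrees with stats::t.test(paired = TRUE)
  pw_p <- pointwise_difference_test(A, B, paired = TRUE)
  p_or <- vapply(seq_len(nvol), function(j)
    t.test(A[, j], B[, j], paired = TRUE)$p.value, numeric(1))
  expect_equal(pw_p$p, p_or, tolerance = 1e-12)
})

test_that("recovery criterion matches construction and brute-force scan", {
  cfg <- recovery_config()
  nvol <- 3660

  # never dips: recovered immediately after stimulation
  tc_flat <- make_group_tc(rep(100, nvol))
  rr0 <- recovery_time(tc_flat, cfg)
  expect_true(rr0$recovered)
  expect_equal(rr0$recovery_minutes, 1 / 30)  # first volume after stim

  # drop to 96%, linear return crossing 98% exactly at stim + 1230 volumes
  trace <- rep(100, nvol)
  post <- 961:nvol
  trace[post] <- 96 + 2 * (post - 961) / 1230
  rr41 <- recovery_time(make_group_tc(trace), cfg)
  expect_true(rr41$recovered)
  expect_equal(rr41$recovery_minutes, 41, tolerance = 0.1)
  expect_identical(rr41$recovery_volume,
                   oracle_recovery_volume(trace, 960, cfg))

  # stays at 97%: censored at the end of the 90 min post window
  trace97 <- rep(100, nvol); trace97[961:nvol] <- 97
  rr97 <- recovery_time(make_group_tc(trace97), cfg)
  expect_false(rr97$recovered)
  expect_equal(rr97$censor_minutes, 90)

  # random noisy traces agree with the oracle exactly
  set.seed(14)
  for (i in 1:5) {
    tr <- 100 + cumsum(rnorm(2000, 0, 0.05))
    cfg_s <- recovery_config(baseline_volumes = c(100, 159),
                             persistence_volumes = 30)
    got <- recovery_time(make_group_tc(tr, stim_volume = 200), cfg_s,
                         stim_volume = 200)
    want <- oracle_recovery_volume(tr, 200, cfg_s)
    if (is.na(want)) expect_false(got$recovered)
    else expect_identical(got$recovery_volume, want)
  }

  expect_error(recovery_time(make_group_tc(rep(100, 500), stim_volume = 300),
                             cfg), "precede")
})

test_that("condition subtraction re-anchors at 100 and is invertible", {
  nvol <- 200
  tgt <- make_group_tc(rep(100, nvol), stim_volume = 50)
  tgt$sd <- rep(1, nvol)
  ctl <- tgt
  sub_same <- subtract_condition(tgt, ctl)
  expect_equal(sub_same$mean, rep(100, nvol))
  expect_equal(sub_same$sd, rep(sqrt(2), nvol))

  tgt2 <- tgt; tgt2$mean <- rep(95, nvol)
  ctl2 <- ctl; ctl2$mean <- rep(98, nvol)
  expect_equal(subtract_condition(tgt2, ctl2)$mean, rep(97, nvol))

  # subtracting then re-adding the control recovers the target exactly
  d <- subtract_condition(tgt2, ctl2)
  expect_equal(d$mean + ctl2$mean - 100, tgt2$mean)

  expect_error(subtract_condition(tgt, make_group_tc(rep(100, 10))), "length")
})
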