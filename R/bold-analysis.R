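# Group-level analysis of BOLD VOI time series: normalization to a grand
# mean of 100%, group mean +/- SD time courses, pointwise Bonferroni t-tests
# between conditions, the 98%-of-baseline recovery criterion, and
# condition-subtraction traces that isolate stimulus- or drug-locked
# effects from the anesthetic's intrinsic drift.

#' Normalize a BOLD series to its grand mean (= 100%)
#'
#' @param series A [bold_series].
#' @return A [bold_series] in percent units (grand mean exactly 100);
#'   `meta$normalized` is set.
#' @export
normalize_bold <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  m <- mean(series$values)
  if (!is.finite(m) || m <= 0)
    stop("grand mean must be positive to normalize", call. = FALSE)
  series$values <- 100 * series$values / m
  series$meta$normalized <- TRUE
  series
}

#' Group mean and SD time course
#'
#' @param series_list List of normalized [bold_series] with identical length
#'   and TR (n >= 2 animals).
#' @param condition Condition label for the group.
#' @return An object of class `group_timecourse` with per-volume `mean` and
#'   sample `sd`, plus `n`, `tr`, `stim_volume` and `condition`.
#' @export
group_timecourse <- function(series_list, condition = NULL) {
  stopifnot(length(series_list) >= 2L)
  lens <- vapply(series_list, function(s) s$n_volumes, integer(1))
  trs <- vapply(series_list, function(s) s$tr, numeric(1))
  if (length(unique(lens)) != 1L)
    stop("series lengths differ: ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  if (length(unique(trs)) != 1L)
    stop("series TRs differ", call. = FALSE)
  mat <- do.call(rbind, lapply(series_list, function(s) s$values))
  sv <- series_list[[1L]]$stim_volume
  structure(list(mean = colMeans(mat),
                 sd = apply(mat, 2L, stats::sd),
                 n = nrow(mat), tr = trs[1L], stim_volume = sv,
                 condition = condition),
            class = "group_timecourse")
}

#' @export
print.group_timecourse <- function(x, ...) {
  cat(sprintf("<group_timecourse>%s n = %d, %d volumes @ TR %g s\n",
              if (is.null(x$condition)) "" else paste0(" '", x$condition, "'"),
              x$n, length(x$mean), x$tr))
  invisible(x)
}

#' Pointwise between-condition t-tests with Bonferroni correction
#'
#' Runs a two-sample equal-variance (pooled) t-test at every volume between
#' the per-animal matrices of two conditions; a volume is significant when
#' its p-value is below `alpha / m`. A paired test per volume is available
#' as an alternative. Volumes with zero pooled variance get p = 1 by
#' convention (their count is reported in `$degenerate`).
#'
#' @param group_a,group_b Numeric matrices, animals x volumes (>= 2 rows
#'   each; for `paired = TRUE`, equal row counts).
#' @param alpha Significance level before correction (default 0.01).
#' @param m Number of tests for the Bonferroni correction; defaults to the
#'   number of volumes tested.
#' @param paired Use a paired t-test per volume instead of the two-sample
#'   test (default FALSE).
#' @return An object of class `pointwise_test` with per-volume `p`,
#'   logical `mask`, `significant_volumes` (0-based indices), `alpha`, `m`,
#'   and `degenerate` (count of zero-variance volumes).
#' @export
pointwise_difference_test <- function(group_a, group_b, alpha = 0.01,
                                      m = NULL, paired = FALSE) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b))
    stop("groups have different numbers of volumes", call. = FALSE)
  if (nrow(group_a) < 2L || nrow(group_b) < 2L)
    stop("need >= 2 animals per group", call. = FALSE)
  n1 <- nrow(group_a); n2 <- nrow(group_b)
  if (paired) {
    if (n1 != n2) stop("paired test needs equal group sizes", call. = FALSE)
    d <- group_a - group_b
    md <- colMeans(d)
    sdd <- apply(d, 2L, stats::sd)
    df <- n1 - 1
    se <- sdd / sqrt(n1)
    tstat <- ifelse(se > 0, md / se, 0)
    p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df), 1)
    degenerate <- sum(se == 0)
  } else {
    m1 <- colMeans(group_a); m2 <- colMeans(group_b)
    v1 <- apply(group_a, 2L, stats::var)
    v2 <- apply(group_b, 2L, stats::var)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- ifelse(se > 0, (m1 - m2) / se, 0)
    p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df), 1)
    degenerate <- sum(se == 0)
  }
  if (is.null(m)) m <- ncol(group_a)
  mask <- p < alpha / m
  structure(list(p = p, mask = mask,
                 significant_volumes = which(mask) - 1L,
                 alpha = alpha, m = m, paired = paired,
                 degenerate = degenerate),
            class = "pointwise_test")
}

#' @export
print.pointwise_test <- function(x, ...) {
  cat(sprintf("<pointwise_test> %s, %d/%d volumes significant at p < %g/%d\n",
              if (x$paired) "paired" else "two-sample equal variance",
              sum(x$mask), length(x$mask), x$alpha, x$m))
  invisible(x)
}

#' Recovery criterion parameters
#'
#' @param baseline_volumes Inclusive 0-based volume range averaged as the
#'   pre-stimulation baseline (default `c(900, 959)`, minutes 30-32 at
#'   TR 2 s).
#' @param threshold_fraction Fraction of the baseline the signal must reach
#'   to count as recovered (default 0.98).
#' @param persistence_volumes Number of consecutive volumes that must stay
#'   at or above threshold (default 60, i.e. 2 min at TR 2 s), so single
#'   noise crossings do not count.
#' @param alpha Significance level carried along for reporting (default 0.01).
#' @return An object of class `recovery_config`.
#' @export
recovery_config <- function(baseline_volumes = c(900, 959),
                            threshold_fraction = 0.98,
                            persistence_volumes = 60, alpha = 0.01) {
  if (!(threshold_fraction > 0 && threshold_fraction <= 1))
    stop("threshold_fraction must be in (0, 1]", call. = FALSE)
  structure(list(baseline_volumes = as.integer(baseline_volumes),
                 threshold_fraction = threshold_fraction,
                 persistence_volumes = as.integer(persistence_volumes),
                 alpha = alpha),
            class = "recovery_config")
}

#' Post-stimulation recovery time of the BOLD baseline
#'
#' The baseline value is the mean of the group-mean trace over the
#' pre-stimulation baseline volumes. Recovery is achieved at the first
#' volume after stimulation from which the group mean stays at or above
#' `threshold_fraction` times that baseline for `persistence_volumes`
#' consecutive volumes; if no such volume exists before the end of the
#' series the result is censored at the end of the recording.
#'
#' @param group A `group_timecourse` (or a plain numeric mean trace).
#' @param cfg A [recovery_config].
#' @param stim_volume 0-based stimulation volume; defaults to the one
#'   stored in `group`.
#' @param tr Repetition time (s); defaults to the one stored in `group`.
#' @return An object of class `recovery_result` with `recovered`,
#'   `recovery_minutes` (NA when censored), `recovery_volume` (0-based),
#'   `baseline_value` and `censor_minutes`.
#' @export
recovery_time <- function(group, cfg = recovery_config(),
                          stim_volume = NULL, tr = NULL) {
  if (inherits(group, "group_timecourse")) {
    trace <- group$mean
    stim_volume <- stim_volume %||% group$stim_volume
    tr <- tr %||% group$tr
  } else {
    trace <- as.numeric(group)
  }
  if (is.null(stim_volume) || is.null(tr))
    stop("stim_volume and tr are required", call. = FALSE)
  stim_volume <- as.integer(stim_volume)
  n <- length(trace)
  bl <- cfg$baseline_volumes
  if (bl[2L] >= stim_volume)
    stop("baseline volume range must precede stim_volume", call. = FALSE)
  baseline_value <- mean(trace[(bl[1L] + 1L):(bl[2L] + 1L)])
  thr <- cfg$threshold_fraction * baseline_value
  ok <- trace >= thr
  # candidate volumes strictly after stimulation (0-based v > stim_volume)
  hit <- first_sustained(ok, stim_volume + 2L, cfg$persistence_volumes)
  censor_minutes <- (n - stim_volume) * tr / 60
  if (!is.na(hit)) {
    v <- hit - 1L  # back to 0-based
    structure(list(recovered = TRUE,
                   recovery_minutes = (v - stim_volume) * tr / 60,
                   recovery_volume = v,
                   baseline_value = baseline_value,
                   censor_minutes = censor_minutes),
              class = "recovery_result")
  } else {
    structure(list(recovered = FALSE, recovery_minutes = NA_real_,
                   recovery_volume = NA_integer_,
                   baseline_value = baseline_value,
                   censor_minutes = censor_minutes),
              class = "recovery_result")
  }
}

#' @export
print.recovery_result <- function(x, ...) {
  if (x$recovered)
    cat(sprintf("<recovery_result> recovered %.1f min after stimulation (baseline %.2f%%)\n",
                x$recovery_minutes, x$baseline_value))
  else
    cat(sprintf("<recovery_result> not recovered within %.1f min (censored)\n",
                x$censor_minutes))
  invisible(x)
}

#' Subtract a control condition from a stimulus condition
#'
#' Removes the anesthetic's intrinsic baseline drift from a stimulated
#' group trace by subtracting the matching unstimulated control trace
#' volume by volume; the difference is re-anchored at 100 so it stays on
#' the percent scale. SDs combine in quadrature (independent groups).
#'
#' @param target,control `group_timecourse` objects of equal length and TR.
#' @return A `group_timecourse` for the difference (n taken from `target`).
#' @export
subtract_condition <- function(target, control) {
  stopifnot(inherits(target, "group_timecourse"),
            inherits(control, "group_timecourse"))
  if (length(target$mean) != length(control$mean))
    stop("time courses have different lengths", call. = FALSE)
  if (abs(target$tr - control$tr) > 1e-9)
    stop("time courses have different TR", call. = FALSE)
  structure(list(mean = target$mean - control$mean + 100,
                 sd = sqrt(target$sd^2 + control$sd^2),
                 n = target$n, tr = target$tr,
                 stim_volume = target$stim_volume,
                 condition = paste0(target$condition %||% "target", " - ",
                                    control$condition %||% "control")),
            class = "group_timecourse")
}

#' Plot a group BOLD time course
#'
#' Mean trace with a +/- SD band, optional rows of dots marking significant
#' volumes (from [pointwise_difference_test()]) and the recovered period
#' (from [recovery_time()]), echoing the usual presentation of such data.
#'
#' @param x A `group_timecourse`.
#' @param test Optional `pointwise_test`.
#' @param recovery Optional `recovery_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.group_timecourse <- function(x, test = NULL, recovery = NULL, ...) {
  tmin <- (seq_along(x$mean) - 1L) * x$tr / 60
  ylim <- range(x$mean - x$sd, x$mean + x$sd)
  graphics::plot(tmin, x$mean, type = "n", xlab = "time (min)",
                 ylab = "BOLD signal (%)", ylim = ylim,
                 main = x$condition %||% "", ...)
  graphics::polygon(c(tmin, rev(tmin)),
                    c(x$mean - x$sd, rev(x$mean + x$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(tmin, x$mean, col = "steelblue4")
  if (!is.null(x$stim_volume))
    graphics::abline(v = x$stim_volume * x$tr / 60, lty = 2, col = "grey40")
  top <- ylim[2L]
  if (!is.null(test))
    graphics::points(tmin[test$mask], rep(top, sum(test$mask)),
                     pch = 16, cex = 0.3, col = "black")
  if (!is.null(recovery) && recovery$recovered) {
    v <- recovery$recovery_volume
    graphics::points(tmin[(v + 1L):length(tmin)],
                     rep(top - 0.02 * diff(ylim), length(tmin) - v),
                     pch = 16, cex = 0.3, col = "red")
  }
  invisible(x)
}
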