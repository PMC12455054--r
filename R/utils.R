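# Internal numerical helpers shared across modules.

#' Trapezoidal integral of a sampled function over an arbitrary interval
#'
#' Integrates linearly-interpolated `y` (sampled at times `t`, strictly
#' increasing, uniform or not) over `[a, b]`. Endpoints falling between
#' samples are handled by linear interpolation, so partial bins are counted
#' pro-rata.
#'
#' @noRd
trapz_interval <- function(t, y, a, b) {
  stopifnot(length(t) == length(y), b >= a)
  if (a == b) return(0)
  a <- max(a, t[1L]); b <- min(b, t[length(t)])
  if (b <= a) return(0)
  inside <- which(t > a & t < b)
  tt <- c(a, t[inside], b)
  yy <- c(stats::approx(t, y, xout = a)$y,
          y[inside],
          stats::approx(t, y, xout = b)$y)
  sum(diff(tt) * (yy[-length(yy)] + yy[-1L]) / 2)
}

#' Centered moving mean with shrinking edge windows
#'
#' Window is `k` samples (forced odd); at the edges the mean is taken over
#' the samples actually available, so the output has no NA padding.
#'
#' @noRd
moving_mean <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || n == 1L) return(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Zero-phase filtering with odd (antisymmetric) edge extension
#'
#' signal::filtfilt alone leaves sizeable transients at the trace ends when
#' the filter has long time constants (e.g. a 0.5 Hz high-pass). Reflecting
#' the signal antisymmetrically about its endpoints before filtering and
#' trimming afterwards suppresses them, mirroring common practice in
#' scientific signal-processing stacks.
#'
#' @noRd
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(as.integer(pad), n - 1L)
  if (pad < 1L) return(signal::filtfilt(filt, x))
  head_ext <- 2 * x[1L] - x[seq(pad + 1L, 2L, by = -1L)]
  tail_ext <- 2 * x[n] - x[seq(n - 1L, n - pad, by = -1L)]
  y <- signal::filtfilt(filt, c(head_ext, x, tail_ext))
  y[seq(pad + 1L, pad + n)]
}

#' First index at or after `from` opening a run of >= len TRUEs
#'
#' Used by both the afterdischarge end detector and the BOLD recovery
#' criterion: a run that starts before `from` but extends past it counts
#' from `from` onwards. Returns NA_integer_ if no qualifying run exists.
#'
#' @noRd
first_sustained <- function(ok, from, len) {
  n <- length(ok)
  if (from > n) return(NA_integer_)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    s <- max(starts[j], as.integer(from))
    if (ends[j] - s + 1L >= len) return(as.integer(s))
  }
  NA_integer_
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the global RNG with `seed`, runs `expr`, then restores the caller's
#' RNG state, so generators are reproducible without clobbering user code.
#'
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed (kept below 2^31)
#' @noRd
child_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
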