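#' Freezing series
#'
#' A freezing series is a binary freezing state over time, stored as a list of
#' half-open bout intervals `[start_s, end_s)` together with the sampling rate
#' `fs` of the equivalent binary vector and the total duration. The interval
#' and binary-vector representations interconvert losslessly at `fs` (bout
#' boundaries are multiples of `1/fs`).
#'
#' @param bouts Two-column matrix (or data.frame) of bout `start_s`, `end_s`;
#'   may have zero rows.
#' @param fs Sampling rate (samples/s) of the equivalent binary vector.
#' @param duration_s Total series duration (s).
#' @return An object of class `freezing_series`.
#' @export
freezing_series <- function(bouts, fs, duration_s) {
  bouts <- matrix(as.numeric(as.matrix(bouts)), ncol = 2,
                  dimnames = list(NULL, c("start_s", "end_s")))
  stopifnot(fs > 0, duration_s > 0)
  if (nrow(bouts) > 0) {
    o <- order(bouts[, 1])
    bouts <- bouts[o, , drop = FALSE]
    if (any(bouts[, 2] <= bouts[, 1]))
      stop("bout end must exceed bout start")
    if (nrow(bouts) > 1 && any(bouts[-1, 1] < bouts[-nrow(bouts), 2]))
      stop("bouts overlap")
    if (bouts[1, 1] < 0 || bouts[nrow(bouts), 2] > duration_s + 1e-9)
      stop("bouts outside [0, duration_s]")
  }
  structure(list(bouts = bouts, fs = fs, duration_s = duration_s),
            class = "freezing_series")
}

#' Convert a freezing series to its binary sample vector
#'
#' Sample i (1-based) covers time `[(i-1)/fs, i/fs)` and is 1 when that
#' sample's start time falls inside a bout.
#'
#' @param series A [freezing_series()].
#' @return Integer vector of 0/1 of length `round(duration_s * fs)`.
#' @export
as_binary <- function(series) {
  stopifnot(inherits(series, "freezing_series"))
  n <- round(series$duration_s * series$fs)
  v <- integer(n)
  if (nrow(series$bouts) > 0) {
    i0 <- round(series$bouts[, 1] * series$fs) + 1L
    i1 <- round(series$bouts[, 2] * series$fs)
    for (k in seq_len(nrow(series$bouts)))
      if (i1[k] >= i0[k]) v[i0[k]:min(i1[k], n)] <- 1L
  }
  v
}

#' Build a freezing series from a binary sample vector
#'
#' @param x Vector of 0/1 freezing states, one per sample.
#' @param fs Sampling rate (samples/s).
#' @return A [freezing_series()] whose bouts are the maximal runs of 1s.
#' @export
freezing_series_from_binary <- function(x, fs) {
  x <- as.integer(x != 0)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  bouts <- cbind(starts[keep], ends[keep]) / fs
  freezing_series(matrix(bouts, ncol = 2), fs, length(x) / fs)
}

#' Total frozen time within an interval
#'
#' Continuous-time intersection of the bout list with `[from, to)`.
#' @param series A [freezing_series()].
#' @param from,to Interval bounds (s).
#' @return Frozen seconds within the interval.
#' @export
frozen_time <- function(series, from, to) {
  b <- series$bouts
  if (nrow(b) == 0) return(0)
  sum(pmax(0, pmin(b[, 2], to) - pmax(b[, 1], from)))
}

#' Detect freezing bouts in a motion trace
#'
#' Freezing is defined as at least `min_bout_s` seconds of immobility:
#' maximal runs of samples whose motion value is at or below `threshold`,
#' lasting at least `min_bout_s` (inclusive boundary: a run of exactly
#' `min_bout_s` counts), become bouts; shorter runs are discarded. Run
#' duration is `run_length / fs`.
#'
#' @param trace A [motion_trace()].
#' @param threshold Motion value at or below which a sample counts as
#'   immobile (same arbitrary units as the trace).
#' @param min_bout_s Minimum immobility duration to count as freezing
#'   (default 1.0 s).
#' @return A [freezing_series()] at the trace's sampling rate.
#' @export
detect_freezing <- function(trace, threshold, min_bout_s = 1.0) {
  stopifnot(inherits(trace, "motion_trace"), is.finite(threshold),
            min_bout_s > 0)
  if (length(trace$values) == 0) stop("empty motion trace")
  fs <- trace$fs
  immobile <- as.integer(trace$values <= threshold)
  r <- rle(immobile)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L & r$lengths / fs >= min_bout_s - 1e-9
  bouts <- cbind(starts[keep], ends[keep]) / fs
  freezing_series(matrix(bouts, ncol = 2), fs, length(immobile) / fs)
}

#' Per-window freezing percentages
#'
#' For each scoring window, the percentage of window time spent frozen,
#' computed by continuous-time interval intersection (independent of the
#' sampling rate).
#'
#' @param series A [freezing_series()].
#' @param windows Two-column matrix of `[start, end)` intervals, e.g. from
#'   [cs_windows()].
#' @return Numeric vector of percentages in `[0, 100]`, one per window.
#' @export
window_freezing <- function(series, windows) {
  stopifnot(inherits(series, "freezing_series"))
  windows <- matrix(as.numeric(as.matrix(windows)), ncol = 2)
  len <- windows[, 2] - windows[, 1]
  if (any(len <= 0)) stop("zero- or negative-length window")
  vapply(seq_len(nrow(windows)), function(i)
    100 * frozen_time(series, windows[i, 1], windows[i, 2]) / len[i],
    numeric(1))
}

#' Freezing during the pre-CS habituation period
#'
#' Percentage of the habituation window `[0, habituation_s)` spent frozen
#' (the 2-min pre-CS period in the canonical protocols).
#'
#' @param series A [freezing_series()].
#' @param schedule A [session_schedule()] with a non-empty habituation window.
#' @return Percentage in `[0, 100]`.
#' @export
pre_cs_freezing <- function(series, schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  if (schedule$habituation_s <= 0) stop("schedule has no habituation window")
  100 * frozen_time(series, 0, schedule$habituation_s) / schedule$habituation_s
}

#' Mean freezing over the last k CS windows
#'
#' @param per_cs Numeric vector of per-CS freezing percentages.
#' @param k Number of final windows to average (default 2, the "2 last CS"
#'   summary).
#' @return Arithmetic mean of the final `k` percentages.
#' @export
last_k_cs_mean <- function(per_cs, k = 2) {
  n <- length(per_cs)
  if (k > n) stop("k exceeds the number of CS windows")
  mean(per_cs[(n - k + 1):n])
}

#' @export
print.freezing_series <- function(x, ...) {
  cat("Freezing series:", nrow(x$bouts), "bouts,",
      sprintf("%.1f", 100 * frozen_time(x, 0, x$duration_s) / x$duration_s),
      "% of", x$duration_s, "s frozen (fs =", x$fs, "Hz)\n")
  invisible(x)
}

#' @export
plot.freezing_series <- function(x, y, col = "steelblue4", ...) {
  plot(NA, xlim = c(0, x$duration_s), ylim = c(0, 1), yaxt = "n",
       xlab = "time (s)", ylab = "", ...)
  if (nrow(x$bouts) > 0)
    rect(x$bouts[, 1], 0.2, x$bouts[, 2], 0.8, col = col, border = NA)
  invisible(x)
}
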