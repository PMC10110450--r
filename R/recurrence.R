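#' Down-sample a freezing series to 1 Hz
#'
#' Second `t` (counted from 0) is scored frozen when the frozen time within
#' `[t, t+1)` is at least 0.5 s (majority rule on continuous coverage).
#'
#' @param series A [freezing_series()] of duration >= 1 s.
#' @return Integer 0/1 vector with one element per whole second.
#' @export
downsample_1hz <- function(series) {
  stopifnot(inherits(series, "freezing_series"))
  n <- floor(series$duration_s)
  if (n < 1) stop("series shorter than 1 s")
  # cumulative frozen time at integer grid points 0..n
  grid <- 0:n
  b <- series$bouts
  cum <- vapply(grid, function(g) {
    if (nrow(b) == 0) 0 else sum(pmax(0, pmin(b[, 2], g) - pmin(b[, 1], g)))
  }, numeric(1))
  as.integer(diff(cum) >= 0.5 - 1e-9)
}

# joint co-occurrence counts sum_t s(t + tau) p(t) for tau = -L..L,
# computed for all lags at once by FFT cross-correlation on a padded
# 2-3-5-smooth length (a prime-length FFT would be quadratic); counts are
# integers, so rounding removes the FFT noise
.xcorr_pad_len <- function(T_, L) stats::nextn(T_ + L + 1, c(2, 3, 5))

.lagged_joint_counts <- function(s, p, L, s_fft = NULL, M = NULL) {
  T_ <- length(p)
  if (is.null(M)) M <- .xcorr_pad_len(T_, L)
  if (is.null(s_fft)) s_fft <- stats::fft(c(as.numeric(s), numeric(M - T_)))
  p_fft <- stats::fft(c(as.numeric(p), numeric(M - T_)))
  cc <- Re(stats::fft(s_fft * Conj(p_fft), inverse = TRUE)) / M
  round(c(cc[M - (L:1) + 1], cc[1:(L + 1)]))
}

#' Lagged co-freezing profile of one dyad
#'
#' For each integer lag tau in `-max_lag_s .. +max_lag_s`, the probability
#' that both animals are frozen when the partner's state is taken `tau`
#' seconds before the subject's: positive lags mean the partner leads.
#' Only overlapping indices contribute (`n_valid = T - |tau|`; no padding).
#'
#' With `statistic = "joint"` (default) the profile is the joint probability
#' `mean(subject(t + tau) * partner(t))`; `"conditional"` divides by the
#' partner's marginal over the same overlap, giving
#' `P(subject frozen at t + tau | partner frozen at t)`.
#'
#' @param subject_1hz,partner_1hz Binary 0/1 vectors at 1 Hz, equal length.
#' @param max_lag_s Maximum lag L in seconds (default 30).
#' @param statistic `"joint"` or `"conditional"`.
#' @return An object of class `cofreeze_profile`: data.frame with columns
#'   `lag_s`, `prob`, `n_valid`.
#' @export
cofreeze_profile <- function(subject_1hz, partner_1hz, max_lag_s = 30,
                             statistic = c("joint", "conditional")) {
  statistic <- match.arg(statistic)
  s <- as.integer(subject_1hz != 0)
  p <- as.integer(partner_1hz != 0)
  T_ <- length(s)
  if (length(p) != T_) stop("subject and partner series differ in length")
  if (T_ < max_lag_s + 2) stop("series shorter than max_lag_s + 2")
  lags <- -max_lag_s:max_lag_s
  nval <- T_ - abs(lags)
  joint <- .lagged_joint_counts(s, p, max_lag_s)
  if (statistic == "joint") {
    prob <- joint / nval
  } else {
    # partner marginal over the overlapping window per lag
    cp <- cumsum(p)
    denom <- numeric(length(lags))
    denom[lags >= 0] <- cp[T_ - lags[lags >= 0]]
    denom[lags < 0] <- cp[T_] - cp[-lags[lags < 0]]
    prob <- ifelse(denom == 0, NA_real_, joint / denom)
  }
  structure(data.frame(lag_s = lags, prob = prob, n_valid = nval),
            class = c("cofreeze_profile", "data.frame"),
            statistic = statistic)
}

#' Shuffled-partner control profile
#'
#' The temporal-alignment null of the co-freezing profile: the partner's
#' 1-Hz bins are randomly permuted `n_shuffles` times (destroying lag
#' structure while preserving the marginal freezing rate), the lagged
#' profile is recomputed for each shuffle, and the per-lag probabilities are
#' averaged into one control profile. The subject vector is left untouched.
#' A circular-shift null (random rotation, preserving the partner's bout
#' structure) is available as an alternative.
#'
#' @inheritParams cofreeze_profile
#' @param n_shuffles Number of shuffles to average (default 100).
#' @param seed Integer seed for the permutation stream.
#' @param null `"permute"` (default, full random permutation) or
#'   `"circular"` (random circular shift).
#' @return A `cofreeze_profile` with attribute `n_shuffles`.
#' @export
shuffled_control_profile <- function(subject_1hz, partner_1hz,
                                     n_shuffles = 100, max_lag_s = 30,
                                     seed = 1L,
                                     statistic = c("joint", "conditional"),
                                     null = c("permute", "circular")) {
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  s <- as.integer(subject_1hz != 0)
  p <- as.integer(partner_1hz != 0)
  T_ <- length(p)
  lags <- -max_lag_s:max_lag_s
  nval <- T_ - abs(lags)
  M <- .xcorr_pad_len(T_, max_lag_s)
  s_fft <- stats::fft(c(as.numeric(s), numeric(M - T_)))
  set.seed(seed)
  acc <- numeric(length(lags))
  for (b in seq_len(n_shuffles)) {
    pp <- if (null == "permute") p[sample.int(T_)]
          else {k <- sample.int(T_, 1); if (k == T_) p else c(p[(k + 1):T_], p[1:k])}
    joint <- .lagged_joint_counts(s, pp, max_lag_s, s_fft = s_fft, M = M)
    if (statistic == "joint") {
      acc <- acc + joint / nval
    } else {
      cp <- cumsum(pp)
      denom <- numeric(length(lags))
      denom[lags >= 0] <- cp[T_ - lags[lags >= 0]]
      denom[lags < 0] <- cp[T_] - cp[-lags[lags < 0]]
      acc <- acc + ifelse(denom == 0, NA_real_, joint / denom)
    }
  }
  out <- cofreeze_profile(s, p, max_lag_s, statistic)
  out$prob <- acc / n_shuffles
  attr(out, "n_shuffles") <- n_shuffles
  attr(out, "null") <- null
  out
}

#' Group-level per-lag comparison of observed and control profiles
#'
#' For each lag, the observed and shuffled-control co-freezing probabilities
#' are compared across dyads with a paired t test, and the resulting P values
#' are Benjamini-Hochberg adjusted across the `2L + 1` lags. Group means and
#' standard errors of both profile families are reported for plotting.
#'
#' A lag where every dyad has identical observed and control probabilities is
#' reported as degenerate with `t = 0`, `p = 1`; a lag with zero variance of
#' the differences but a non-zero mean is degenerate with infinite `t` and
#' `p = 0` (flagged, not an error).
#'
#' @param observed,control Lists of [cofreeze_profile()] objects, one
#'   observed/control pair per dyad (same order, same lags); at least 3 dyads.
#' @return An object of class `group_profile_result`: data.frame with columns
#'   `lag_s`, `mean_observed`, `sem_observed`, `mean_control`, `sem_control`,
#'   `t`, `df`, `p`, `q`, `degenerate`.
#' @export
group_lag_tests <- function(observed, control) {
  if (length(observed) != length(control))
    stop("observed and control dyad counts differ")
  n <- length(observed)
  if (n < 3) stop("need at least 3 dyads")
  lags <- observed[[1]]$lag_s
  for (pr in c(observed, control))
    if (!identical(pr$lag_s, lags)) stop("profiles have mismatched lags")
  O <- do.call(rbind, lapply(observed, function(x) x$prob))
  C <- do.call(rbind, lapply(control, function(x) x$prob))
  D <- O - C
  m <- colMeans(D)
  sdv <- apply(D, 2, stats::sd)
  # zero-variance differences (up to rounding) are degenerate, not an error
  degen <- sdv <= 1e-12 * pmax(1, abs(m))
  se <- sdv / sqrt(n)
  tt <- ifelse(!degen, m / se, ifelse(abs(m) <= 1e-12, 0, sign(m) * Inf))
  p <- ifelse(is.finite(tt) & !degen, 2 * stats::pt(-abs(tt), df = n - 1),
              ifelse(abs(m) <= 1e-12, 1, 0))
  res <- data.frame(
    lag_s = lags,
    mean_observed = colMeans(O),
    sem_observed = apply(O, 2, stats::sd) / sqrt(n),
    mean_control = colMeans(C),
    sem_control = apply(C, 2, stats::sd) / sqrt(n),
    t = tt, df = n - 1, p = p, q = bh_fdr(p), degenerate = degen)
  structure(res, class = c("group_profile_result", "data.frame"),
            n_dyads = n)
}

#' @export
plot.cofreeze_profile <- function(x, y, ...) {
  plot(x$lag_s, x$prob, type = "l", xlab = "lag (s, + = partner leads)",
       ylab = "P(co-freezing)", ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' @export
plot.group_profile_result <- function(x, y, ...) {
  ylim <- range(c(x$mean_observed + x$sem_observed,
                  x$mean_observed - x$sem_observed,
                  x$mean_control + x$sem_control,
                  x$mean_control - x$sem_control))
  plot(x$lag_s, x$mean_observed, type = "l", ylim = ylim, col = "firebrick",
       xlab = "lag (s, + = partner leads)", ylab = "P(co-freezing)", ...)
  lines(x$lag_s, x$mean_control, col = "grey40")
  arrows(x$lag_s, x$mean_observed - x$sem_observed,
         x$lag_s, x$mean_observed + x$sem_observed,
         length = 0.02, angle = 90, code = 3, col = "firebrick")
  arrows(x$lag_s, x$mean_control - x$sem_control,
         x$lag_s, x$mean_control + x$sem_control,
         length = 0.02, angle = 90, code = 3, col = "grey40")
  legend("topright", c("observed", "shuffled control"), lty = 1,
         col = c("firebrick", "grey40"), bty = "n")
  invisible(x)
}
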