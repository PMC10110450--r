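#' Motion trace
#'
#' Per-sample motion magnitude (arbitrary units, e.g. frame-difference pixel
#' counts) at a fixed sampling rate.
#'
#' @param values Numeric vector of motion magnitudes, one per sample.
#' @param fs Sampling rate (samples/s).
#' @param t0 Time of the first sample (s).
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(values, fs, t0 = 0) {
  stopifnot(fs > 0, all(is.finite(values)))
  structure(list(values = as.numeric(values), fs = fs, t0 = t0),
            class = "motion_trace")
}

#' Configuration of the coupled dyadic freezing simulator
#'
#' Parameters of the coupled two-state Markov model used to generate paired
#' freezing series with known ground truth. Each animal's freezing state
#' evolves in discrete steps of `1/fs` s: a non-freezing animal starts
#' freezing with per-step probability `p_on_base` (multiplied by `cs_gain`
#' inside CS + 20 s windows), and a freezing animal stops with probability
#' `p_off_base`. The subject is additionally coupled to its partner: when the
#' partner was frozen `lag_s` seconds earlier, the subject's onset probability
#' is multiplied by `(1 + coupling)` and its offset probability divided by
#' `(1 + coupling)`; probabilities are clamped to `[0, 1]`. `coupling = 0`
#' gives statistically independent series.
#'
#' Defaults emulate a day-5 extinction-test session: freezing is mostly
#' CS-evoked (baseline onset 0.005/s, raised 15-fold inside CS + 20 s
#' windows) with long bouts (mean `1/p_off_base` ~ 67 s) and a stationary
#' no-CS freezing fraction `p_on_base / (p_on_base + p_off_base)` = 0.25;
#' on the 15-CS test schedule this yields session freezing around 60-85%,
#' the range the fear-extinction literature reports for such tests.
#'
#' @param fs Sampling rate (steps/s), >= 1.
#' @param p_on_base Per-step baseline 0 -> 1 (freezing onset) probability.
#' @param p_off_base Per-step 1 -> 0 (freezing offset) probability.
#' @param cs_gain Multiplicative onset gain inside CS + 20 s windows.
#' @param coupling Dimensionless coupling strength kappa >= 0.
#' @param lag_s Lag delta (s) by which the partner's state leads its
#'   influence on the subject.
#' @param seed Integer seed; fully determines the simulated dyad.
#' @return An object of class `dyad_sim_config`.
#' @export
dyad_sim_config <- function(fs = 1, p_on_base = 0.005, p_off_base = 0.015,
                            cs_gain = 15, coupling = 0, lag_s = 0,
                            seed = 1L) {
  stopifnot(fs >= 1, p_on_base >= 0, p_on_base <= 1,
            p_off_base >= 0, p_off_base <= 1,
            is.finite(cs_gain), cs_gain >= 0,
            is.finite(coupling), coupling >= 0, lag_s >= 0)
  structure(list(fs = fs, p_on_base = p_on_base, p_off_base = p_off_base,
                 cs_gain = cs_gain, coupling = coupling, lag_s = lag_s,
                 seed = as.integer(seed)),
            class = "dyad_sim_config")
}

# onset gain per step: cs_gain inside any CS+tail window, else 1
.cs_gain_vector <- function(schedule, fs, n_steps, cs_gain, tail_s = 20) {
  g <- rep(1, n_steps)
  if (length(schedule$cs_onsets) > 0) {
    w <- cs_windows(schedule, tail_s)
    t <- (seq_len(n_steps) - 1) / fs
    for (i in seq_len(nrow(w)))
      g[t >= w[i, 1] & t < w[i, 2]] <- cs_gain
  }
  g
}

# simulate one two-state chain; p_on may be modulated per step by `gain`
# and both transitions by the lagged partner state (NULL for the partner)
.simulate_chain <- function(n, p_on, p_off, gain, partner = NULL,
                            coupling = 0, lag_steps = 0L) {
  u <- stats::runif(n)
  x <- integer(n)
  state <- 0L
  for (t in seq_len(n)) {
    mod <- 1
    if (!is.null(partner)) {
      ps <- if (t - lag_steps >= 1) partner[t - lag_steps] else 0L
      mod <- 1 + coupling * ps
    }
    if (state == 0L) {
      if (u[t] < min(1, max(0, p_on * gain[t] * mod))) state <- 1L
    } else {
      if (u[t] < min(1, max(0, p_off / mod))) state <- 0L
    }
    x[t] <- state
  }
  x
}

#' Simulate a coupled freezing dyad
#'
#' Generates paired binary freezing series for one dyad under the coupled
#' two-state Markov model of [dyad_sim_config()]. The partner evolves
#' autonomously (its onset probability scaled by `cs_gain` inside CS + 20 s
#' windows); the subject follows the same rule with both transition
#' probabilities modulated by the partner's state `lag_s` seconds earlier,
#' so positive coupling raises both entry into and persistence of
#' co-freezing. The partner's state before the session start is taken as 0.
#'
#' @param schedule A [session_schedule()].
#' @param config A [dyad_sim_config()]; its seed fully determines the output.
#' @return An object of class `simulated_dyad`: list with `subject` and
#'   `partner` ([freezing_series()] objects sharing `fs` and length) and
#'   `truth` (the exact config used).
#' @export
simulate_dyad <- function(schedule, config) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(config, "dyad_sim_config"))
  if (config$lag_s >= schedule$session_length_s)
    stop("lag_s must be smaller than the session length")
  fs <- config$fs
  n <- round(schedule$session_length_s * fs)
  lag_steps <- round(config$lag_s * fs)
  gain <- .cs_gain_vector(schedule, fs, n, config$cs_gain)
  set.seed(config$seed)
  partner <- .simulate_chain(n, config$p_on_base, config$p_off_base, gain)
  subject <- .simulate_chain(n, config$p_on_base, config$p_off_base, gain,
                             partner = partner, coupling = config$coupling,
                             lag_steps = lag_steps)
  structure(list(subject = freezing_series_from_binary(subject, fs),
                 partner = freezing_series_from_binary(partner, fs),
                 truth = config),
            class = "simulated_dyad")
}

#' Simulate a motion trace from a known freezing series
#'
#' Motion samples are `immobile_amp` plus Gaussian noise during freezing and
#' `active_amp` plus noise otherwise, so the freezing series is exactly
#' recoverable by thresholding at the midpoint
#' `(immobile_amp + active_amp) / 2` as long as the amplitudes are separated
#' by more than six noise standard deviations.
#'
#' @param freezing A [freezing_series()] giving the ground-truth bouts.
#' @param immobile_amp,active_amp Mean motion value during immobility /
#'   activity (arbitrary units).
#' @param noise_sd Gaussian noise SD; must satisfy
#'   `active_amp - immobile_amp > 6 * noise_sd`.
#' @param seed Integer seed.
#' @return A [motion_trace()] at the freezing series' sampling rate.
#' @export
simulate_motion <- function(freezing, immobile_amp = 1, active_amp = 10,
                            noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(freezing, "freezing_series"), noise_sd >= 0)
  if (active_amp - immobile_amp <= 6 * noise_sd)
    stop("amplitudes not separable: need active_amp - immobile_amp > 6 * noise_sd")
  b <- as_binary(freezing)
  set.seed(seed)
  vals <- ifelse(b == 1L, immobile_amp, active_amp) +
    stats::rnorm(length(b), 0, noise_sd)
  motion_trace(vals, freezing$fs)
}

#' Simulate ultrasonic vocalisation events in two frequency bands
#'
#' Two independent homogeneous Poisson streams of USV events, one around
#' 22 kHz (negative-affect alarm calls) and one around 50 kHz
#' (positive-affect calls). Counts per band are Poisson with mean
#' `rate * duration_s / 60`; peak frequencies are drawn uniformly within
#' +/- 3 kHz (22-kHz band) or +/- 10 kHz (50-kHz band) of the band centre,
#' so every event classifies into its generating band under the default
#' bands of [classify_usv()].
#'
#' @param rate_22,rate_50 Emission rates (events/min), >= 0.
#' @param duration_s Recording duration (s).
#' @param band_centers Band centre frequencies (kHz), default `c(22, 50)`.
#' @param seed Integer seed.
#' @return A data.frame with columns `time_s`, `peak_khz`, sorted by time.
#' @export
simulate_usv <- function(rate_22, rate_50, duration_s,
                         band_centers = c(22, 50), seed = 1L) {
  stopifnot(rate_22 >= 0, rate_50 >= 0, duration_s > 0,
            length(band_centers) == 2)
  set.seed(seed)
  n22 <- stats::rpois(1, rate_22 * duration_s / 60)
  n50 <- stats::rpois(1, rate_50 * duration_s / 60)
  ev <- data.frame(
    time_s = c(stats::runif(n22, 0, duration_s),
               stats::runif(n50, 0, duration_s)),
    peak_khz = c(band_centers[1] + stats::runif(n22, -3, 3),
                 band_centers[2] + stats::runif(n50, -10, 10)))
  ev[order(ev$time_s), , drop = FALSE]
}

#' Simulate a confined open-field trajectory
#'
#' Reflected Gaussian random walk within a square arena `[0, arena_side_m]^2`
#' starting at the centre: each step adds independent Gaussian increments and
#' positions are folded back at the walls.
#'
#' @param arena_side_m Arena side (m), default 1 (the 1 m x 1 m open field).
#' @param duration_s Session duration (s).
#' @param step_sd_m Per-step displacement SD (m), > 0 (0 allowed for a
#'   stationary point).
#' @param fs Sampling rate (samples/s).
#' @param seed Integer seed.
#' @return A data.frame with columns `time_s`, `x_m`, `y_m`.
#' @export
simulate_trajectory <- function(arena_side_m = 1, duration_s = 420,
                                step_sd_m = 0.02, fs = 25, seed = 1L) {
  stopifnot(arena_side_m > 0, duration_s > 0, step_sd_m >= 0, fs > 0)
  n <- round(duration_s * fs)
  set.seed(seed)
  reflect <- function(z) {
    # fold into [0, side] (triangle wave)
    z <- z %% (2 * arena_side_m)
    ifelse(z > arena_side_m, 2 * arena_side_m - z, z)
  }
  x <- reflect(arena_side_m / 2 + cumsum(c(0, stats::rnorm(n - 1, 0, step_sd_m))))
  y <- reflect(arena_side_m / 2 + cumsum(c(0, stats::rnorm(n - 1, 0, step_sd_m))))
  data.frame(time_s = (seq_len(n) - 1) / fs, x_m = x, y_m = y)
}

#' @export
print.simulated_dyad <- function(x, ...) {
  cat("Simulated dyad (kappa =", x$truth$coupling,
      ", lag =", x$truth$lag_s, "s, seed =", x$truth$seed, ")\n")
  cat("  subject: "); print(x$subject)
  cat("  partner: "); print(x$partner)
  invisible(x)
}
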