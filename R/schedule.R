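#' Session schedule
#'
#' A session schedule describes one behavioural session: an initial
#' habituation window, the onsets and common duration of the conditioned
#' stimuli (CS), the inter-trial interval (ITI) and the total session length.
#' Times are seconds from session start.
#'
#' @param habituation_s Length of the initial habituation window (s).
#' @param cs_onsets Numeric vector of CS onset times (s), strictly increasing;
#'   may be empty for CS-free sessions.
#' @param cs_duration_s Duration of each CS (s).
#' @param iti_s Inter-trial interval between CS offset and the next onset (s).
#' @param session_length_s Total session length (s).
#' @param metadata Optional named list of stimulus attributes (tone frequency,
#'   sound level, shock amplitude, ...); informational only.
#'
#' @return An object of class `session_schedule`.
#' @seealso [make_schedule()] for the canonical protocols, [cs_windows()].
#' @export
session_schedule <- function(habituation_s, cs_onsets, cs_duration_s, iti_s,
                             session_length_s, metadata = list()) {
  stopifnot(is.numeric(habituation_s), habituation_s >= 0,
            is.numeric(cs_onsets),
            is.numeric(cs_duration_s), cs_duration_s >= 0,
            is.numeric(iti_s), iti_s >= 0,
            is.numeric(session_length_s), session_length_s > 0)
  cs_onsets <- as.numeric(cs_onsets)
  if (length(cs_onsets) > 0) {
    if (any(diff(cs_onsets) <= 0))
      stop("cs_onsets must be strictly increasing")
    if (cs_onsets[1] < habituation_s)
      stop("first CS onset precedes the end of habituation")
    if (max(cs_onsets) + cs_duration_s + 20 > session_length_s)
      stop("CS + 20 s window extends beyond session_length_s")
  }
  structure(
    list(habituation_s = habituation_s,
         cs_onsets = cs_onsets,
         cs_duration_s = cs_duration_s,
         iti_s = iti_s,
         session_length_s = session_length_s,
         metadata = metadata),
    class = "session_schedule")
}

# canonical protocol table: n CS, 20 s tones, 60 s ITIs, 120 s habituation
.protocols <- list(
  conditioning        = list(n_cs = 5L),
  extinction_training = list(n_cs = 30L),
  extinction_test     = list(n_cs = 15L),
  cage_exposure       = list(n_cs = 0L)
)

#' Build a canonical session schedule
#'
#' Returns the schedule of one of the four canonical protocols of the
#' five-day dyadic fear-extinction paradigm:
#' \describe{
#'   \item{`conditioning`}{120 s habituation, 5 CS of 20 s, 60 s ITI (day 1).}
#'   \item{`extinction_training`}{120 s habituation, 30 CS, 60 s ITI (days 2-4,
#'     the extinguished partner).}
#'   \item{`extinction_test`}{120 s habituation, 15 CS, 60 s ITI (day 5).}
#'   \item{`cage_exposure`}{no CS; same total duration as
#'     `extinction_training` (days 2-4, the non-extinguished subject, which
#'     spends the same amount of time in the cage).}
#' }
#' CS onsets follow from the arithmetic of the schedule: the k-th onset (from
#' 0) is `habituation + k * (cs_duration + iti)` seconds.
#'
#' @param protocol One of `"conditioning"`, `"extinction_training"`,
#'   `"extinction_test"`, `"cage_exposure"`.
#' @param overrides Optional named list overriding `habituation_s`,
#'   `cs_duration_s`, `iti_s`, `n_cs`, `session_length_s` or `metadata`
#'   before the schedule is assembled.
#' @return A [session_schedule()] object.
#' @examples
#' make_schedule("conditioning")$cs_onsets  # 120 200 280 360 440
#' @export
make_schedule <- function(protocol = c("conditioning", "extinction_training",
                                       "extinction_test", "cage_exposure"),
                          overrides = list()) {
  protocol <- match.arg(protocol)
  pars <- list(habituation_s = 120, cs_duration_s = 20, iti_s = 60,
               n_cs = .protocols[[protocol]]$n_cs,
               session_length_s = NULL, metadata = list())
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(pars))
    if (length(bad) > 0)
      stop("unknown override field(s): ", paste(bad, collapse = ", "))
    pars[names(overrides)] <- overrides
  }
  period <- pars$cs_duration_s + pars$iti_s
  if (protocol == "cage_exposure" && is.null(pars$session_length_s)) {
    # same time in the cage as an extinction-training session
    pars$session_length_s <- 120 + .protocols$extinction_training$n_cs * period
    pars$n_cs <- 0L
  }
  onsets <- if (pars$n_cs > 0) pars$habituation_s + period * (seq_len(pars$n_cs) - 1)
            else numeric(0)
  if (is.null(pars$session_length_s))
    pars$session_length_s <- pars$habituation_s + pars$n_cs * period
  session_schedule(pars$habituation_s, onsets, pars$cs_duration_s, pars$iti_s,
                   pars$session_length_s, pars$metadata)
}

#' CS scoring windows
#'
#' One scoring interval per CS, spanning the CS presentation plus the
#' following `tail_s` seconds (the CS + 20 s window by default; freezing that
#' starts during the CS typically outlasts it).
#'
#' @param schedule A [session_schedule()].
#' @param tail_s Seconds appended after CS offset (default 20).
#' @return A two-column matrix with one row per CS: `start_s`, `end_s`
#'   (half-open intervals `[start, end)`).
#' @export
cs_windows <- function(schedule, tail_s = 20) {
  stopifnot(inherits(schedule, "session_schedule"), tail_s >= 0)
  on <- schedule$cs_onsets
  cbind(start_s = on, end_s = on + schedule$cs_duration_s + tail_s)
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("Session schedule:", x$session_length_s, "s;",
      length(x$cs_onsets), "CS of", x$cs_duration_s, "s;",
      "habituation", x$habituation_s, "s; ITI", x$iti_s, "s\n")
  invisible(x)
}
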