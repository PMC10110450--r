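#' Read and write the plain-text data formats
#'
#' Freezing series and motion traces travel as two-column CSV
#' (`time_s,value`); trajectories as `time_s,x_m,y_m`; USV events as
#' `time_s,peak_khz`; ethograms as `behavior,start_s,end_s`; schedules as
#' JSON. Freezing CSVs hold the binary sample vector at the series'
#' sampling rate, so the interval representation round-trips exactly.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the parsed
#'   object.
#' @name cofreezr-io
NULL

#' @rdname cofreezr-io
#' @export
write_freezing_csv <- function(x, path) {
  stopifnot(inherits(x, "freezing_series"))
  v <- as_binary(x)
  utils::write.csv(data.frame(time_s = (seq_along(v) - 1) / x$fs, value = v),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname cofreezr-io
#' @param fs Sampling rate when the time column alone is ambiguous
#'   (inferred from the time step when omitted).
#' @export
read_freezing_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)))
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time_s))
  freezing_series_from_binary(d$value, fs)
}

#' @rdname cofreezr-io
#' @export
write_motion_csv <- function(x, path) {
  stopifnot(inherits(x, "motion_trace"))
  utils::write.csv(data.frame(
    time_s = x$t0 + (seq_along(x$values) - 1) / x$fs, value = x$values),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname cofreezr-io
#' @export
read_motion_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)))
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time_s))
  motion_trace(d$value, fs, t0 = d$time_s[1])
}

#' @rdname cofreezr-io
#' @export
read_ethogram_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("behavior", "start_s", "end_s") %in% names(d)))
  d
}

#' @rdname cofreezr-io
#' @export
write_schedule_json <- function(x, path) {
  stopifnot(inherits(x, "session_schedule"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cofreezr-io
#' @export
read_schedule_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  session_schedule(d$habituation_s, d$cs_onsets, d$cs_duration_s, d$iti_s,
                   d$session_length_s,
                   if (is.null(d$metadata)) list() else as.list(d$metadata))
}

#' Write a co-freezing profile or group result as TSV
#'
#' Profiles are written as `lag_s`, `prob`, `n_valid`; group results with
#' their means, SEMs and per-lag test columns.
#'
#' @param x A `cofreeze_profile` or `group_profile_result`.
#' @param path File path.
#' @export
write_profile_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
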