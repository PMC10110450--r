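#' Canonical ethogram behaviours
#'
#' The five behaviours scored during dyadic test sessions: quiescence
#' (motionless), mesh sniffing (sniffing the wire-mesh divider), prosocial
#' behaviour (direct contact through the mesh), cage exploration (horizontal
#' investigation of non-social cues) and rearing (standing on hind legs).
#' @export
ethogram_behaviors <- c("quiescence", "mesh_sniffing", "prosocial",
                        "cage_exploration", "rearing")

#' Total duration per ethogram behaviour
#'
#' Sums the interval durations of each behaviour over the whole session,
#' clipping intervals to `[0, session_length_s]`. Intervals of different
#' behaviours may overlap; overlapping intervals within one behaviour are an
#' error (they would double-count time).
#'
#' @param records Data.frame with columns `behavior`, `start_s`, `end_s`
#'   (half-open intervals, `end_s > start_s`).
#' @param session_length_s Session length (s).
#' @return Named numeric vector of seconds, one element per canonical
#'   behaviour (plus any additional labels present), zeros for unobserved
#'   behaviours.
#' @export
ethogram_durations <- function(records, session_length_s) {
  stopifnot(session_length_s > 0)
  levels_all <- union(ethogram_behaviors, unique(as.character(records$behavior)))
  out <- stats::setNames(numeric(length(levels_all)), levels_all)
  if (nrow(records) == 0) return(out)
  stopifnot(all(c("behavior", "start_s", "end_s") %in% names(records)))
  if (any(records$end_s <= records$start_s))
    stop("interval end must exceed start")
  for (b in unique(as.character(records$behavior))) {
    iv <- records[records$behavior == b, , drop = FALSE]
    iv <- iv[order(iv$start_s), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start_s[-1] < iv$end_s[-nrow(iv)]))
      stop("overlapping intervals within behaviour '", b, "'")
    out[b] <- sum(pmax(0, pmin(iv$end_s, session_length_s) -
                         pmax(iv$start_s, 0)))
  }
  out
}

#' Classify USV events into frequency bands
#'
#' Counts events whose peak frequency falls into the ~22-kHz band (alarm
#' calls) or the ~50-kHz band (appetitive calls); events between or outside
#' the bands are counted as unclassified. Band edges are half-open
#' `[low, high)` and the two bands must be disjoint.
#'
#' @param events Data.frame with columns `time_s`, `peak_khz` (e.g. from
#'   [simulate_usv()]).
#' @param band_22,band_50 Band limits in kHz; defaults `[18, 32)` and
#'   `[35, 90)`.
#' @return Named integer vector `c(band_22, band_50, unclassified)`.
#' @export
classify_usv <- function(events, band_22 = c(18, 32), band_50 = c(35, 90)) {
  stopifnot(length(band_22) == 2, length(band_50) == 2,
            band_22[1] < band_22[2], band_50[1] < band_50[2])
  if (max(band_22[1], band_50[1]) < min(band_22[2], band_50[2]))
    stop("USV bands overlap")
  f <- events$peak_khz
  in22 <- f >= band_22[1] & f < band_22[2]
  in50 <- f >= band_50[1] & f < band_50[2]
  c(band_22 = sum(in22), band_50 = sum(in50),
    unclassified = sum(!in22 & !in50))
}

#' Open-field metrics from a tracked trajectory
#'
#' Locomotion and centre-zone measures of a single open-field session. The
#' centre zone is the concentric square of side
#' `center_fraction * arena_side_m`. An entry is an outside-to-inside
#' transition of the tracked point; starting inside the zone does not count
#' as an entry. Centre time sums the inter-sample intervals whose starting
#' sample lies in the zone. Distance is the summed Euclidean length of
#' consecutive steps; mean velocity is distance over session duration. The
#' mean entry duration is total centre time divided by the number of
#' entries (NA for zero entries); the mean entry velocity averages, over
#' entry episodes, the path length within the episode divided by its
#' duration.
#'
#' @param traj Data.frame with monotone `time_s` and positions `x_m`, `y_m`
#'   (>= 2 samples).
#' @param arena_side_m Arena side (m), default 1.
#' @param center_fraction Centre-zone side as a fraction of the arena side,
#'   default 0.5.
#' @return A list of class `openfield_metrics`: `total_distance_m`,
#'   `mean_velocity_mps`, `center_entries`, `center_time_s`,
#'   `mean_entry_duration_s`, `mean_entry_velocity_mps`.
#' @export
openfield_metrics <- function(traj, arena_side_m = 1, center_fraction = 0.5) {
  stopifnot(all(c("time_s", "x_m", "y_m") %in% names(traj)))
  n <- nrow(traj)
  if (n < 2) stop("need at least 2 trajectory samples")
  if (any(diff(traj$time_s) <= 0)) stop("time_s must be strictly increasing")
  lo <- arena_side_m * (1 - center_fraction) / 2
  hi <- arena_side_m * (1 + center_fraction) / 2
  inside <- traj$x_m >= lo & traj$x_m <= hi & traj$y_m >= lo & traj$y_m <= hi
  dt <- diff(traj$time_s)
  steps <- sqrt(diff(traj$x_m)^2 + diff(traj$y_m)^2)
  total_dist <- sum(steps)
  duration <- traj$time_s[n] - traj$time_s[1]
  entries_idx <- which(!inside[-n] & inside[-1]) + 1L  # first inside sample
  center_time <- sum(dt[inside[-n]])
  n_entries <- length(entries_idx)
  entry_vel <- NA_real_
  if (n_entries > 0) {
    vels <- vapply(entries_idx, function(i0) {
      i1 <- i0
      while (i1 < n && inside[i1 + 1L]) i1 <- i1 + 1L
      # episode spans samples i0..i1; its time extends to sample i1+1 (exit)
      # or the series end
      iend <- min(i1 + 1L, n)
      dur <- traj$time_s[iend] - traj$time_s[i0]
      if (dur <= 0) return(NA_real_)
      sum(steps[i0:(iend - 1L)]) / dur
    }, numeric(1))
    entry_vel <- mean(vels, na.rm = TRUE)
  }
  structure(list(
    total_distance_m = total_dist,
    mean_velocity_mps = total_dist / duration,
    center_entries = n_entries,
    center_time_s = center_time,
    mean_entry_duration_s = if (n_entries > 0) center_time / n_entries else NA_real_,
    mean_entry_velocity_mps = entry_vel),
    class = "openfield_metrics")
}

#' @export
print.openfield_metrics <- function(x, ...) {
  cat("Open-field metrics:\n")
  cat(sprintf("  distance: %.2f m, mean velocity: %.3f m/s\n",
              x$total_distance_m, x$mean_velocity_mps))
  cat(sprintf("  center: %d entries, %.1f s total", x$center_entries,
              x$center_time_s))
  if (!is.na(x$mean_entry_duration_s))
    cat(sprintf(", %.2f s/entry, %.3f m/s on entry",
                x$mean_entry_duration_s, x$mean_entry_velocity_mps))
  cat("\n")
  invisible(x)
}
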