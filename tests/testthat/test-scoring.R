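test_that("freezing detection honours the 1 s inclusive boundary", {
  fs <- 25
  mk_trace <- function(immobile_runs_s, total_s = 10) {
    v <- rep(10, total_s * fs)
    for (r in immobile_runs_s) {
      i0 <- round(r[1] * fs) + 1; i1 <- round(r[2] * fs)
      v[i0:i1] <- 1
    }
    motion_trace(v, fs)
  }
  # 0.8 s of immobility: below the minimum, no bout
  fr <- detect_freezing(mk_trace(list(c(2, 2.8))), threshold = 5)
  expect_equal(nrow(fr$bouts), 0)
  # exactly 1.0 s: counts (inclusive boundary)
  fr <- detect_freezing(mk_trace(list(c(2, 3))), threshold = 5)
  expect_equal(fr$bouts, cbind(start_s = 2, end_s = 3))
  # empty trace errors
  expect_error(detect_freezing(motion_trace(numeric(0), fs), 5), "empty")
})

test_that("freezing detection inverts simulate_motion on random fixtures", {
  set.seed(101)
  for (rep in 1:25) {
    fs <- sample(c(10, 25), 1)
    dur <- 120
    # random non-overlapping bouts of >= 1 s on a 1/fs grid
    n_b <- sample(1:6, 1)
    starts <- sort(sample(seq(0, dur - 10, by = 1 / fs), n_b))
    lens <- round(runif(n_b, 1, 4) * fs) / fs
    ends <- pmin(starts + lens, dur)
    bouts <- NULL
    last_end <- -Inf
    for (j in seq_len(n_b)) {
      if (starts[j] >= last_end + 1 / fs) {  # >= 1 active sample between
        bouts <- rbind(bouts, c(starts[j], ends[j]))
        last_end <- ends[j]
      }
    }
    fr <- freezing_series(bouts, fs, dur)
    tr <- simulate_motion(fr, seed = rep)
    rec <- detect_freezing(tr, threshold = 5.5)
    expect_equal(rec$bouts, fr$bouts)
  }
})

test_that("detection is idempotent on its own binary output", {
  fr <- freezing_series(rbind(c(1, 3), c(5, 10)), fs = 25, duration_s = 20)
  tr <- motion_trace(1 - as_binary(fr), 25)  # 0 while frozen, 1 otherwise
  rec <- detect_freezing(tr, threshold = 0.5)
  expect_equal(rec$bouts, fr$bouts)
})

test_that("window freezing matches per-sample counting and basic identities", {
  sched <- make_schedule("extinction_test")
  w <- cs_windows(sched)
  # fully frozen session
  full <- freezing_series(rbind(c(0, sched$session_length_s)), fs = 25,
                          duration_s = sched$session_length_s)
  expect_equal(window_freezing(full, w), rep(100, 15))
  # frozen exactly during the 20 s CS of a 40 s window
  one <- freezing_series(rbind(c(120, 140)), fs = 25,
                         duration_s = sched$session_length_s)
  expect_equal(window_freezing(one, w)[1], 50)
  expect_equal(window_freezing(one, w)[2], 0)
  # random simulated series against the per-sample oracle
  d <- simulate_dyad(sched, dyad_sim_config(fs = 5, seed = 17))
  pct <- window_freezing(d$subject, w)
  oracle <- vapply(seq_len(nrow(w)), function(i)
    oracle_window_pct(d$subject, w[i, 1], w[i, 2]), numeric(1))
  expect_equal(pct, oracle)
  expect_true(all(pct >= 0 & pct <= 100))
  expect_error(window_freezing(full, cbind(10, 10)), "window")
})

test_that("pre-CS freezing scores the habituation window", {
  sched <- make_schedule("extinction_test")
  none <- freezing_series(rbind(c(150, 200)), fs = 25,
                          duration_s = sched$session_length_s)
  expect_equal(pre_cs_freezing(none, sched), 0)
  all_hab <- freezing_series(rbind(c(0, 120)), fs = 25,
                             duration_s = sched$session_length_s)
  expect_equal(pre_cs_freezing(all_hab, sched), 100)
  d <- simulate_dyad(sched, dyad_sim_config(fs = 5, seed = 23))
  expect_equal(pre_cs_freezing(d$partner, sched),
               oracle_window_pct(d$partner, 0, 120))
  no_hab <- make_schedule("cage_exposure",
                          overrides = list(habituation_s = 0))
  expect_error(pre_cs_freezing(none, no_hab), "habituation")
})

test_that("last-k CS mean is the tail average", {
  expect_equal(last_k_cs_mean(c(0, 0, 0, 100, 100), k = 2), 100)
  x <- runif(15, 0, 100)
  expect_equal(last_k_cs_mean(x, k = 15), mean(x))
  expect_equal(last_k_cs_mean(x, k = 3), mean(x[13:15]))
  expect_error(last_k_cs_mean(x, k = 16), "exceeds")
})

test_that("ethogram durations sum clipped intervals per behaviour", {
  empty <- data.frame(behavior = character(), start_s = numeric(),
                      end_s = numeric())
  expect_true(all(ethogram_durations(empty, 600) == 0))

  one <- data.frame(behavior = "rearing", start_s = 10, end_s = 25)
  expect_equal(unname(ethogram_durations(one, 600)["rearing"]), 15)

  # random non-overlapping intervals vs interval-by-interval oracle
  set.seed(7)
  beh <- sample(ethogram_behaviors, 30, replace = TRUE)
  starts <- sort(runif(30, 0, 580))
  ends <- pmin(starts + runif(30, 0.5, 15), 600)
  # enforce within-behaviour disjointness by construction per behaviour
  recs <- do.call(rbind, lapply(split(seq_len(30), beh), function(idx) {
    idx <- idx[order(starts[idx])]
    keep <- rep(TRUE, length(idx))
    hi <- -Inf
    for (j in seq_along(idx)) {
      if (starts[idx[j]] < hi) keep[j] <- FALSE
      else hi <- ends[idx[j]]
    }
    data.frame(behavior = beh[idx[keep]], start_s = starts[idx[keep]],
               end_s = ends[idx[keep]])
  }))
  dur <- ethogram_durations(recs, 600)
  for (b in unique(recs$behavior)) {
    iv <- recs[recs$behavior == b, ]
    expect_equal(unname(dur[b]), sum(iv$end_s - iv$start_s))
  }

  # behaviours tiling the session sum to its length
  tile <- data.frame(behavior = rep(ethogram_behaviors, each = 1),
                     start_s = seq(0, 480, by = 120),
                     end_s = seq(120, 600, by = 120))
  expect_equal(sum(ethogram_durations(tile, 600)), 600)

  overlap <- data.frame(behavior = c("rearing", "rearing"),
                        start_s = c(0, 5), end_s = c(10, 15))
  expect_error(ethogram_durations(overlap, 600), "overlap")
})

test_that("USV classification separates bands and flags the gap", {
  ev <- data.frame(time_s = 1:3, peak_khz = c(22, 33, 50))
  cnt <- classify_usv(ev)
  expect_equal(unname(cnt), c(1L, 1L, 1L))
  expect_error(classify_usv(ev, band_22 = c(18, 40), band_50 = c(35, 90)),
               "overlap")
})

test_that("open-field metrics follow the zone conventions", {
  # stationary point in the centre: no entries, full centre time
  still <- data.frame(time_s = seq(0, 10, by = 0.5), x_m = 0.5, y_m = 0.5)
  m <- openfield_metrics(still)
  expect_equal(m$center_entries, 0)
  expect_equal(m$center_time_s, 10)
  expect_true(is.na(m$mean_entry_duration_s))

  # square path along the walls: never inside
  wall <- data.frame(
    time_s = 0:4,
    x_m = c(0.05, 0.95, 0.95, 0.05, 0.05),
    y_m = c(0.05, 0.05, 0.95, 0.95, 0.05))
  mw <- openfield_metrics(wall)
  expect_equal(mw$center_entries, 0)
  expect_equal(mw$center_time_s, 0)
  expect_equal(mw$total_distance_m, 4 * 0.9)

  # entries counted as outside -> inside transitions, zone [0.25, 0.75]
  path <- data.frame(
    time_s = 0:7,
    x_m = c(0.1, 0.5, 0.5, 0.1, 0.1, 0.5, 0.5, 0.1),
    y_m = 0.5)
  mp <- openfield_metrics(path)
  expect_equal(mp$center_entries, 2)
  expect_equal(mp$center_time_s, 4)  # samples 2,3 and 6,7 start inside
  expect_equal(mp$mean_entry_duration_s, 2)

  # per-sample zone-membership oracle on a simulated walk
  tr <- simulate_trajectory(duration_s = 60, step_sd_m = 0.08, fs = 5,
                            seed = 12)
  mm <- openfield_metrics(tr)
  inside <- tr$x_m >= 0.25 & tr$x_m <= 0.75 & tr$y_m >= 0.25 & tr$y_m <= 0.75
  expect_equal(mm$center_entries, sum(!head(inside, -1) & tail(inside, -1)))
  expect_equal(mm$center_time_s, sum(0.2 * head(inside, -1)))
  expect_error(openfield_metrics(still[1, ]), "2")
})

test_that("open-field distance is invariant to rigid motions", {
  tr <- simulate_trajectory(duration_s = 30, step_sd_m = 0.03, fs = 5,
                            seed = 2)
  d0 <- openfield_metrics(tr)$total_distance_m
  th <- 0.7
  rot <- data.frame(time_s = tr$time_s,
                    x_m = cos(th) * tr$x_m - sin(th) * tr$y_m + 0.2,
                    y_m = sin(th) * tr$x_m + cos(th) * tr$y_m + 0.1)
  expect_equal(openfield_metrics(rot)$total_distance_m, d0)
})
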