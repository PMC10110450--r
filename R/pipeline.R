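#' Assemble an experiment manifest
#'
#' A manifest bundles everything one analysis run needs: the animal table
#' (id, pair, role, group, schedule name), the per-animal freezing series,
#' optional ethogram and USV event tables, and the analysis settings
#' (seed, permutation count, recurrence parameters, planned comparisons).
#'
#' @param animals Data.frame with columns `animal_id`, `pair_id`, `role`
#'   (`"subject"` or `"partner"`), `group`, `schedule` (a protocol name
#'   accepted by [make_schedule()]).
#' @param series Named list of [freezing_series()], one per `animal_id`.
#' @param settings Named list; recognised entries (with defaults):
#'   `seed` (1), `n_perm` (10000), `max_lag_s` (30), `n_shuffles` (100),
#'   `comparisons` (list of length-2 group vectors, default all group
#'   pairs), `recurrence_groups` (character, default: groups with >= 3
#'   complete pairs).
#' @param ethograms Optional named list of ethogram data.frames
#'   (`behavior`, `start_s`, `end_s`) keyed by `animal_id`.
#' @param usv Optional named list of USV event data.frames
#'   (`time_s`, `peak_khz`) keyed by `animal_id`.
#' @return An object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(animals, series, settings = list(),
                                ethograms = NULL, usv = NULL) {
  defaults <- list(seed = 1L, n_perm = 10000L, max_lag_s = 30L,
                   n_shuffles = 100L, comparisons = NULL,
                   recurrence_groups = NULL)
  settings <- utils::modifyList(defaults, settings)
  structure(list(animals = animals, series = series, settings = settings,
                 ethograms = ethograms, usv = usv),
            class = "experiment_manifest")
}

#' Validate an experiment manifest
#'
#' Returns machine-readable findings rather than raising errors, so callers
#' can present all problems at once; [run_experiment()] refuses to run when
#' any finding has level `"error"`.
#'
#' @param manifest An [experiment_manifest()].
#' @return Data.frame with columns `level` (`"error"`/`"warning"`),
#'   `field`, `message`; zero rows when the manifest is clean.
#' @export
validate_manifest <- function(manifest) {
  f <- list()
  add <- function(level, field, message)
    f[[length(f) + 1]] <<- data.frame(level = level, field = field,
                                      message = message)
  a <- manifest$animals
  need <- c("animal_id", "pair_id", "role", "group", "schedule")
  if (!is.data.frame(a) || !all(need %in% names(a))) {
    add("error", "animals", paste("animal table must have columns:",
                                  paste(need, collapse = ", ")))
    return(do.call(rbind, f))
  }
  if (nrow(a) == 0) add("error", "animals", "empty animal table")
  if (anyDuplicated(a$animal_id))
    add("error", "animal_id", "duplicated animal ids")
  bad_role <- setdiff(unique(a$role), c("subject", "partner"))
  if (length(bad_role) > 0)
    add("error", "role", paste("unknown role(s):",
                               paste(bad_role, collapse = ", ")))
  bad_sched <- setdiff(unique(a$schedule), names(.protocols))
  if (length(bad_sched) > 0)
    add("error", "schedule", paste("unknown schedule name(s):",
                                   paste(bad_sched, collapse = ", ")))
  for (pid in unique(stats::na.omit(a$pair_id))) {
    m <- a[!is.na(a$pair_id) & a$pair_id == pid, ]
    if (nrow(m) != 2)
      add("error", "pair_id",
          paste0("pair '", pid, "' has ", nrow(m), " member(s), needs 2"))
    else if (!setequal(m$role, c("subject", "partner")))
      add("error", "pair_id",
          paste0("pair '", pid, "' needs one subject and one partner"))
  }
  missing_series <- setdiff(a$animal_id, names(manifest$series))
  if (length(missing_series) > 0)
    add("error", "series", paste("no freezing series for:",
                                 paste(missing_series, collapse = ", ")))
  for (id in intersect(a$animal_id, names(manifest$series))) {
    s <- manifest$series[[id]]
    if (!inherits(s, "freezing_series")) {
      add("error", "series", paste0("'", id, "' is not a freezing_series"))
      next
    }
    sched_name <- a$schedule[a$animal_id == id][1]
    if (sched_name %in% names(.protocols)) {
      sched <- make_schedule(sched_name)
      if (abs(s$duration_s - sched$session_length_s) > 1)
        add("warning", "series",
            paste0("'", id, "' duration ", s$duration_s,
                   " s differs from schedule length ",
                   sched$session_length_s, " s"))
    }
  }
  comps <- manifest$settings$comparisons
  if (!is.null(comps))
    for (cmp in comps)
      if (length(cmp) != 2 || !all(cmp %in% a$group))
        add("error", "comparisons",
            paste("comparison references unknown group:",
                  paste(cmp, collapse = " vs ")))
  out <- if (length(f) > 0) do.call(rbind, f)
         else data.frame(level = character(), field = character(),
                         message = character())
  out
}

# deterministic short hash (polynomial rolling hash of the JSON text)
# for provenance
.manifest_digest <- function(manifest) {
  txt <- jsonlite::toJSON(list(animals = manifest$animals,
                               settings = manifest$settings),
                          auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(txt)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis battery on an experiment manifest
#'
#' Scores every animal's session (per-CS freezing percentages in CS + 20 s
#' windows, pre-CS freezing, mean of the last 2 CS), builds per-group
#' descriptive tables (mean +/- SEM per CS), runs the group comparison
#' battery on the subject animals (permutation one-way ANOVA omnibus on the
#' per-animal mean CS freezing, permutation t tests for the planned
#' comparisons, Benjamini-Hochberg FDR across the comparison list),
#' summarises ethogram durations and USV band counts when provided, and
#' runs the dyadic co-freezing recurrence analysis (observed and
#' shuffled-control profiles, per-lag paired t with FDR) for every group
#' with at least 3 complete dyads. Deterministic given the manifest's
#' seeds.
#'
#' @param manifest An [experiment_manifest()]; must validate without
#'   errors.
#' @return An object of class `cofreeze_report`; see the package vignette
#'   for the component tables.
#' @export
run_experiment <- function(manifest) {
  findings <- validate_manifest(manifest)
  if (any(findings$level == "error")) {
    stop("manifest validation failed:\n",
         paste(" -", findings$message[findings$level == "error"],
               collapse = "\n"))
  }
  a <- manifest$animals
  st <- manifest$settings
  schedules <- lapply(stats::setNames(unique(a$schedule), unique(a$schedule)),
                      make_schedule)
  # per-animal scoring
  score_rows <- lapply(seq_len(nrow(a)), function(i) {
    id <- a$animal_id[i]
    s <- manifest$series[[id]]
    sched <- schedules[[a$schedule[i]]]
    w <- cs_windows(sched)
    per_cs <- if (nrow(w) > 0) window_freezing(s, w) else numeric(0)
    data.frame(animal_id = id, pair_id = a$pair_id[i], role = a$role[i],
               group = a$group[i],
               pre_cs_pct = if (sched$habituation_s > 0)
                 pre_cs_freezing(s, sched) else NA_real_,
               mean_cs_pct = if (length(per_cs)) mean(per_cs) else NA_real_,
               last2_cs_pct = if (length(per_cs) >= 2)
                 last_k_cs_mean(per_cs, 2) else NA_real_)
  })
  summary_table <- do.call(rbind, score_rows)
  per_cs_long <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    id <- a$animal_id[i]
    sched <- schedules[[a$schedule[i]]]
    w <- cs_windows(sched)
    if (nrow(w) == 0) return(NULL)
    data.frame(animal_id = id, group = a$group[i], role = a$role[i],
               cs = seq_len(nrow(w)),
               freezing_pct = window_freezing(manifest$series[[id]], w))
  }))
  descriptives <- NULL
  if (!is.null(per_cs_long)) {
    agg <- split(per_cs_long, list(per_cs_long$group, per_cs_long$cs),
                 drop = TRUE)
    descriptives <- do.call(rbind, lapply(agg, function(d)
      data.frame(group = d$group[1], cs = d$cs[1],
                 mean = mean(d$freezing_pct),
                 sem = stats::sd(d$freezing_pct) / sqrt(nrow(d)),
                 n = nrow(d))))
    descriptives <- descriptives[order(descriptives$group, descriptives$cs), ]
    rownames(descriptives) <- NULL
  }
  # comparison battery on the subject animals
  subj <- summary_table[summary_table$role == "subject" &
                          !is.na(summary_table$mean_cs_pct), ]
  groups_tab <- split(subj$mean_cs_pct, subj$group)
  groups_tab <- groups_tab[vapply(groups_tab, length, 1L) >= 2]
  omnibus <- NULL
  comparisons <- NULL
  if (length(groups_tab) >= 2) {
    omnibus <- perm_oneway_anova(groups_tab, n_perm = st$n_perm,
                                 seed = st$seed)
    comps <- st$comparisons
    if (is.null(comps))
      comps <- utils::combn(names(groups_tab), 2, simplify = FALSE)
    rows <- lapply(seq_along(comps), function(j) {
      g1 <- comps[[j]][1]; g2 <- comps[[j]][2]
      r <- perm_ttest(groups_tab[[g1]], groups_tab[[g2]],
                      n_perm = st$n_perm, seed = st$seed + j)
      data.frame(group1 = g1, group2 = g2, t = r$value, p = r$p_raw,
                 n_perm = r$n_perm)
    })
    comparisons <- do.call(rbind, rows)
    comparisons$q <- bh_fdr(comparisons$p)
  }
  # ethogram / USV summaries
  ethogram_summary <- NULL
  if (!is.null(manifest$ethograms)) {
    rows <- lapply(names(manifest$ethograms), function(id) {
      sched <- schedules[[a$schedule[a$animal_id == id][1]]]
      dur <- ethogram_durations(manifest$ethograms[[id]],
                                sched$session_length_s)
      data.frame(animal_id = id, group = a$group[a$animal_id == id][1],
                 behavior = names(dur), seconds = unname(dur))
    })
    ethogram_summary <- do.call(rbind, rows)
  }
  usv_summary <- NULL
  if (!is.null(manifest$usv)) {
    rows <- lapply(names(manifest$usv), function(id) {
      cnt <- classify_usv(manifest$usv[[id]])
      data.frame(animal_id = id, group = a$group[a$animal_id == id][1],
                 band = names(cnt), count = unname(cnt))
    })
    usv_summary <- do.call(rbind, rows)
  }
  # dyadic recurrence per group
  rec_groups <- st$recurrence_groups
  pairs <- stats::na.omit(unique(a$pair_id))
  pair_group <- vapply(pairs, function(p)
    a$group[!is.na(a$pair_id) & a$pair_id == p][1], character(1))
  if (is.null(rec_groups)) {
    tab <- table(pair_group)
    rec_groups <- names(tab)[tab >= 3]
  }
  recurrence <- list()
  for (g in rec_groups) {
    gpairs <- pairs[pair_group == g]
    if (length(gpairs) < 3) next
    obs <- list(); ctl <- list()
    for (j in seq_along(gpairs)) {
      p <- gpairs[j]
      sid <- a$animal_id[a$pair_id %in% p & a$role == "subject"]
      pid <- a$animal_id[a$pair_id %in% p & a$role == "partner"]
      s1 <- downsample_1hz(manifest$series[[sid]])
      p1 <- downsample_1hz(manifest$series[[pid]])
      obs[[j]] <- cofreeze_profile(s1, p1, max_lag_s = st$max_lag_s)
      ctl[[j]] <- shuffled_control_profile(
        s1, p1, n_shuffles = st$n_shuffles, max_lag_s = st$max_lag_s,
        seed = st$seed + 7919 * j)
    }
    recurrence[[g]] <- group_lag_tests(obs, ctl)
  }
  structure(list(
    summary_table = summary_table,
    per_cs = per_cs_long,
    descriptives = descriptives,
    omnibus = omnibus,
    comparisons = comparisons,
    ethogram_summary = ethogram_summary,
    usv_summary = usv_summary,
    recurrence = recurrence,
    findings = findings,
    provenance = list(seed = st$seed, n_perm = st$n_perm,
                      max_lag_s = st$max_lag_s, n_shuffles = st$n_shuffles,
                      manifest_digest = .manifest_digest(manifest),
                      package_version =
                        as.character(utils::packageVersion("cofreezr")))),
    class = "cofreeze_report")
}

#' @export
print.cofreeze_report <- function(x, ...) {
  cat("Dyadic fear-extinction analysis report",
      sprintf("(manifest %s, seed %d)\n", x$provenance$manifest_digest,
              x$provenance$seed))
  tab <- table(x$summary_table$group, x$summary_table$role)
  cat("Animals:\n"); print(tab)
  if (!is.null(x$omnibus)) { cat("Omnibus: "); print(x$omnibus) }
  if (!is.null(x$comparisons)) {
    cat("Planned comparisons (FDR-adjusted):\n")
    print(format(x$comparisons, digits = 4), row.names = FALSE)
  }
  for (g in names(x$recurrence))
    cat(sprintf("Recurrence [%s]: %d/%d lags with q < 0.05\n", g,
                sum(x$recurrence[[g]]$q < 0.05), nrow(x$recurrence[[g]])))
  invisible(x)
}

#' Simulate a complete dyadic experiment
#'
#' Builds an [experiment_manifest()] of simulated dyads with known ground
#' truth, one freezing series per animal, for end-to-end pipeline tests.
#' Each group is simulated from the base configuration modified by its
#' entry in `groups`; per-dyad seeds are drawn from one seeded stream so
#' the whole experiment is reproducible from `seed`.
#'
#' @param groups Named list; each element is a list with `n_pairs` and
#'   optional [dyad_sim_config()] field overrides (e.g.
#'   `list(coupled = list(n_pairs = 6, coupling = 5))`).
#' @param protocol Schedule name for all animals (default
#'   `"extinction_test"`).
#' @param base_config A [dyad_sim_config()] supplying defaults.
#' @param settings Analysis settings forwarded to [experiment_manifest()].
#' @param seed Integer master seed.
#' @return An `experiment_manifest` whose `truth` attribute records the
#'   per-group generating configurations.
#' @export
simulate_experiment <- function(groups, protocol = "extinction_test",
                                base_config = dyad_sim_config(),
                                settings = list(), seed = 1L) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  sched <- make_schedule(protocol)
  set.seed(seed)
  n_total <- sum(vapply(groups, function(g) as.integer(g$n_pairs), 1L))
  pair_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  animals <- NULL; series <- list(); truth <- list(); k <- 0L
  for (g in names(groups)) {
    gdef <- groups[[g]]
    overrides <- gdef[setdiff(names(gdef), "n_pairs")]
    cfg0 <- utils::modifyList(unclass(base_config), overrides)
    truth[[g]] <- cfg0
    for (i in seq_len(gdef$n_pairs)) {
      k <- k + 1L
      cfg <- do.call(dyad_sim_config,
                     utils::modifyList(cfg0, list(seed = pair_seeds[k])))
      dy <- simulate_dyad(sched, cfg)
      pid <- sprintf("%s_pair%02d", g, i)
      ids <- paste0(pid, c("_subj", "_part"))
      animals <- rbind(animals, data.frame(
        animal_id = ids, pair_id = pid,
        role = c("subject", "partner"), group = g, schedule = protocol))
      series[[ids[1]]] <- dy$subject
      series[[ids[2]]] <- dy$partner
    }
  }
  if (is.null(settings$seed)) settings$seed <- seed
  m <- experiment_manifest(animals, series, settings)
  attr(m, "truth") <- truth
  m
}

#' @export
print.experiment_manifest <- function(x, ...) {
  cat("Experiment manifest:", nrow(x$animals), "animals,",
      length(unique(stats::na.omit(x$animals$pair_id))), "pairs,",
      length(unique(x$animals$group)), "group(s)\n")
  invisible(x)
}
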