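#' Statistical test result
#'
#' Lightweight container for one test: the statistic, its degrees of freedom,
#' the raw P value, an optional FDR-adjusted q value, a method tag, and for
#' resampling tests the permutation count and seed.
#'
#' @param statistic_name One of `"t"`, `"F"`, `"W"`, `"U"`, `"SW"`.
#' @param value Statistic value.
#' @param df Degrees of freedom (scalar or length-2 for F).
#' @param p_raw Raw two-sided P value.
#' @param method Method tag.
#' @param q Optional FDR-adjusted P.
#' @param n_perm,seed Optional permutation count / seed.
#' @param degenerate TRUE when the statistic is undefined or infinite
#'   (zero-variance input) and the reported values follow a convention.
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(statistic_name, value, df, p_raw, method,
                        q = NA_real_, n_perm = NA_integer_,
                        seed = NA_integer_, degenerate = FALSE) {
  structure(list(statistic_name = statistic_name, value = value, df = df,
                 p_raw = p_raw, q = q, method = method, n_perm = n_perm,
                 seed = seed, degenerate = degenerate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, ": ", x$statistic_name, " = ",
      format(x$value, digits = 4), ", df = ",
      paste(format(x$df, digits = 4), collapse = ", "),
      ", P = ", format(x$p_raw, digits = 4), sep = "")
  if (!is.na(x$q)) cat(", q =", format(x$q, digits = 4))
  if (!is.na(x$n_perm)) cat(" (", x$n_perm, " permutations)", sep = "")
  if (isTRUE(x$degenerate)) cat(" [degenerate]")
  cat("\n")
  invisible(x)
}

# classical one-way F from a value vector and group factor
.oneway_F <- function(z, g) {
  N <- length(z)
  k <- nlevels(g)
  sums <- tapply(z, g, sum)
  ns <- tabulate(g)
  G <- sum(z)
  ssb <- sum(sums^2 / ns) - G^2 / N
  ssw <- sum(z^2) - sum(sums^2 / ns)
  if (ssw <= 0) return(if (ssb <= 1e-12) NaN else Inf)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' Permutation one-way ANOVA
#'
#' Classical one-way F on the observed data; the P value is estimated by
#' randomly reassigning group labels `n_perm` times and applying the add-one
#' estimator `P = (1 + #{F* >= F}) / (1 + n_perm)`, so the estimate is never
#' smaller than `1 / (n_perm + 1)`. The F statistic and degrees of freedom
#' are reported for reference; inference rests on the permutation P.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return A [stat_result()] with `statistic_name = "F"`.
#' @export
perm_oneway_anova <- function(groups, n_perm = 10000, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2), n_perm >= 1)
  z <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  N <- length(z); k <- nlevels(g)
  F_obs <- .oneway_F(z, g)
  if (is.nan(F_obs))  # all values identical: F undefined, P = 1 by convention
    return(stat_result("F", 0, c(k - 1, N - k), 1, "permutation one-way ANOVA",
                       n_perm = as.integer(n_perm), seed = as.integer(seed),
                       degenerate = TRUE))
  set.seed(seed)
  idx <- split(seq_len(N), g)
  ns <- lengths(idx)
  Q <- sum(z^2); G <- sum(z)
  count <- 0L
  for (b in seq_len(n_perm)) {
    zp <- z[sample.int(N)]
    sums <- vapply(idx, function(ii) sum(zp[ii]), numeric(1))
    ssb <- sum(sums^2 / ns) - G^2 / N
    ssw <- Q - sum(sums^2 / ns)
    Fp <- if (ssw <= 0) (if (ssb <= 1e-12) NaN else Inf)
          else (ssb / (k - 1)) / (ssw / (N - k))
    if (!is.nan(Fp) && Fp >= F_obs - 1e-12) count <- count + 1L
  }
  stat_result("F", F_obs, c(k - 1, N - k), (1 + count) / (1 + n_perm),
              "permutation one-way ANOVA",
              n_perm = as.integer(n_perm), seed = as.integer(seed))
}

# pooled-variance two-sample t from group-1 sufficient statistics
.pooled_t_from_sums <- function(sA, qA, n1, S, Q, N) {
  n2 <- N - n1
  m1 <- sA / n1; m2 <- (S - sA) / n2
  ss1 <- qA - sA^2 / n1
  ss2 <- (Q - qA) - (S - sA)^2 / n2
  sp2 <- (ss1 + ss2) / (N - 2)
  if (sp2 <= 0) return(if (abs(m1 - m2) < 1e-12) 0 else Inf * sign(m1 - m2))
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Permutation two-sample t test
#'
#' Pooled-variance t on the observed samples; the two-sided P value is
#' estimated by permuting the pooled observations between the two labels
#' `n_perm` times with the add-one estimator
#' `P = (1 + #{|t*| >= |t|}) / (1 + n_perm)`.
#'
#' @param x,y Numeric samples (each >= 2 observations).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A [stat_result()] with `statistic_name = "t"`.
#' @export
perm_ttest <- function(x, y, n_perm = 10000, seed = 1L) {
  stopifnot(length(x) >= 2, length(y) >= 2, n_perm >= 1)
  n1 <- length(x); N <- n1 + length(y)
  z <- c(x, y)
  S <- sum(z); Q <- sum(z^2)
  t_obs <- .pooled_t_from_sums(sum(x), sum(x^2), n1, S, Q, N)
  if (!is.finite(t_obs))  # zero pooled variance, unequal means
    return(stat_result("t", t_obs, N - 2, 1 / (n_perm + 1),
                       "permutation t test (pooled)",
                       n_perm = as.integer(n_perm), seed = as.integer(seed),
                       degenerate = TRUE))
  if (t_obs == 0 && stats::var(z) == 0)  # all values identical
    return(stat_result("t", 0, N - 2, 1, "permutation t test (pooled)",
                       n_perm = as.integer(n_perm), seed = as.integer(seed),
                       degenerate = TRUE))
  set.seed(seed)
  # canonical scheme: permute the sorted pool and draw the smaller group
  # size, so the estimate is invariant to the order of the two samples
  zs <- sort(z)
  m <- min(n1, N - n1)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(N, m)
    tp <- .pooled_t_from_sums(sum(zs[idx]), sum(zs[idx]^2), m, S, Q, N)
    if (abs(tp) >= abs(t_obs) - 1e-12) count <- count + 1L
  }
  stat_result("t", t_obs, N - 2, (1 + count) / (1 + n_perm),
              "permutation t test (pooled)",
              n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' Classical univariate split-plot decomposition for one between-subjects
#' factor (group) and one within-subjects factor (time) on a balanced time
#' grid: the group effect is tested against subject-within-group error; time
#' and the group x time interaction against the within-subject residual.
#' Group sizes may differ; every subject must be measured at every time
#' point exactly once. F and P are uncorrected univariate values; the
#' Greenhouse-Geisser epsilon is reported alongside for reference when
#' `gg_epsilon = TRUE`.
#'
#' @param table Long-format data.frame with columns `subject`, `group`,
#'   `time`, `value`: each subject in exactly one group.
#' @param gg_epsilon Also estimate the Greenhouse-Geisser sphericity epsilon
#'   from the pooled within-group covariance (default FALSE).
#' @return An object of class `mixed_anova`: data.frame with one row per
#'   stratum (`group`, `subject_within_group`, `time`, `group_x_time`,
#'   `residual`) and columns `df`, `SS`, `MS`, `F`, `p`; the
#'   Greenhouse-Geisser epsilon, when requested, is attached as attribute
#'   `gg_epsilon`.
#' @export
mixed_rm_anova <- function(table, gg_epsilon = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("subject", "group", "time", "value") %in% names(table)))
  subject <- factor(table$subject)
  group <- factor(table$group)
  time <- factor(table$time)
  y <- as.numeric(table$value)
  if (anyNA(y)) stop("missing values in 'value'")
  # one group per subject
  if (any(rowSums(table(subject, group) > 0) != 1))
    stop("each subject must belong to exactly one group")
  # balanced time grid
  if (any(table(subject, time) != 1))
    stop("unbalanced design: every subject needs exactly one value per time")
  sg <- tapply(as.integer(group), subject, function(v) v[1])
  ns_per_group <- tabulate(sg, nbins = nlevels(group))
  if (any(ns_per_group < 2)) stop("every group needs at least 2 subjects")
  a <- nlevels(time)
  N <- nlevels(subject)
  k <- nlevels(group)
  grand <- mean(y)
  M_s <- tapply(y, subject, mean)            # subject means
  M_g <- tapply(y, group, mean)              # group means
  M_t <- tapply(y, time, mean)               # time means (subject-weighted)
  M_gt <- tapply(y, list(group, time), mean) # cell means
  ss_group <- a * sum(ns_per_group * (M_g - grand)^2)
  ss_subj <- a * sum((M_s - M_g[sg])^2)
  ss_time <- N * sum((M_t - grand)^2)
  ss_inter <- sum(ns_per_group *
                    rowSums((M_gt - outer(M_g, rep(1, a)) -
                               outer(rep(1, k), M_t) + grand)^2))
  resid <- y - M_s[subject] - M_gt[cbind(group, time)] + M_g[group]
  ss_resid <- sum(resid^2)
  df <- c(k - 1, N - k, a - 1, (k - 1) * (a - 1), (N - k) * (a - 1))
  SS <- c(ss_group, ss_subj, ss_time, ss_inter, ss_resid)
  MS <- SS / df
  Fv <- c(MS[1] / MS[2], NA, MS[3] / MS[5], MS[4] / MS[5], NA)
  Fv[c(1, 3, 4)][SS[c(1, 3, 4)] == 0] <- 0  # zero effect SS: F = 0
  pv <- c(stats::pf(Fv[1], df[1], df[2], lower.tail = FALSE), NA,
          stats::pf(Fv[3], df[3], df[5], lower.tail = FALSE),
          stats::pf(Fv[4], df[4], df[5], lower.tail = FALSE), NA)
  out <- data.frame(
    effect = c("group", "subject_within_group", "time", "group_x_time",
               "residual"),
    df = df, SS = SS, MS = MS, F = Fv, p = pv)
  if (gg_epsilon) {
    # pooled within-group covariance of the subject x time matrix
    Y <- matrix(y[order(subject, time)], nrow = N, ncol = a, byrow = TRUE)
    Yc <- Y - M_g[sg][row(Y)]
    Sg <- stats::cov(Yc)
    dbar <- mean(diag(Sg)); mbar <- mean(Sg)
    eps <- (a^2 * (dbar - mbar)^2) /
      ((a - 1) * (sum(Sg^2) - 2 * a * sum(rowMeans(Sg)^2) + a^2 * mbar^2))
    attr(out, "gg_epsilon") <- eps
  }
  structure(out, class = c("mixed_anova", "data.frame"))
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed (split-plot) repeated-measures ANOVA\n")
  print.data.frame(format(as.data.frame(x), digits = 5), row.names = FALSE)
  if (!is.null(attr(x, "gg_epsilon")))
    cat("Greenhouse-Geisser epsilon:",
        format(attr(x, "gg_epsilon"), digits = 4), "\n")
  invisible(x)
}

#' Two-sample t tests from printed summary statistics
#'
#' Reconstruct an unpaired t test from group means, SDs and sizes, as needed
#' to check statistics reported only as summaries. `pooled_t_summary` uses
#' the pooled-variance t with `df = n1 + n2 - 2`; `welch_t_summary` uses the
#' Welch statistic with Welch-Satterthwaite degrees of freedom. Two-sided P
#' from the t distribution.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return A [stat_result()] with `statistic_name = "t"`.
#' @export
pooled_t_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  if (se == 0) {
    if (m1 == m2) return(stat_result("t", 0, df, 1, "unpaired t test (pooled)",
                                     degenerate = TRUE))
    return(stat_result("t", sign(m2 - m1) * Inf, df, 0,
                       "unpaired t test (pooled)", degenerate = TRUE))
  }
  t <- (m2 - m1) / se
  stat_result("t", t, df, 2 * stats::pt(-abs(t), df), "unpaired t test (pooled)")
}

#' @rdname pooled_t_summary
#' @export
welch_t_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  if (se == 0) {
    if (m1 == m2) return(stat_result("t", 0, n1 + n2 - 2, 1, "Welch's t test",
                                     degenerate = TRUE))
    return(stat_result("t", sign(m2 - m1) * Inf, n1 + n2 - 2, 0,
                       "Welch's t test", degenerate = TRUE))
  }
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  t <- (m2 - m1) / se
  stat_result("t", t, df, 2 * stats::pt(-abs(t), df), "Welch's t test")
}

#' Paired t test
#'
#' One-sample t on the differences `x - y`, `df = n - 1`, two-sided P.
#' Zero-variance differences are flagged as degenerate: all-zero differences
#' give `t = 0`, `P = 1`; a constant non-zero difference gives infinite t.
#'
#' @param x,y Paired numeric samples of equal length >= 2.
#' @return A [stat_result()] with `statistic_name = "t"`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  sdv <- stats::sd(d)
  if (sdv <= 1e-12 * max(1, abs(mean(d)))) {
    if (all(d == 0))
      return(stat_result("t", 0, n - 1, 1, "paired t test", degenerate = TRUE))
    return(stat_result("t", sign(mean(d)) * Inf, n - 1, 0, "paired t test",
                       degenerate = TRUE))
  }
  t <- mean(d) / (sdv / sqrt(n))
  stat_result("t", t, n - 1, 2 * stats::pt(-abs(t), n - 1), "paired t test")
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' W is the sum of ranks of the positive differences after dropping zero
#' differences (signed-rank convention) and ranking the absolute
#' differences. For `n <= exact_max_n` non-zero untied differences the
#' two-sided P is exact, from the full null distribution of W over all
#' `2^n` sign assignments; otherwise a tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param x,y Paired numeric samples (or `y = NULL` for one-sample
#'   differences already in `x`).
#' @param exact_max_n Largest n for which the exact distribution is used
#'   (default 25; exact requires untied non-zero differences).
#' @return A [stat_result()] with `statistic_name = "W"`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max_n && !ties) {
    # exact null distribution of W (all 2^n sign patterns)
    p <- min(1, 2 * min(stats::psignrank(W, n),
                        stats::psignrank(W - 1, n, lower.tail = FALSE)))
    return(stat_result("W", W, n, p, "Wilcoxon signed-rank (exact)"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  stat_result("W", W, n, min(1, 2 * stats::pnorm(-abs(z))),
              "Wilcoxon signed-rank (normal approx.)")
}

#' Mann-Whitney U test
#'
#' U counts the pairs `(i, j)` with `x_i > y_j` (plus half the ties), i.e.
#' the rank-sum form `U = R_x - n1 (n1 + 1) / 2`. For tie-free samples with
#' `min(n1, n2) <= exact_max_n` the two-sided P is exact, from the full null
#' distribution of U over all `choose(n1 + n2, n1)` arrangements; otherwise
#' a tie-corrected normal approximation with continuity correction is used.
#' Swapping the samples maps U to `n1 * n2 - U` and leaves P unchanged.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max_n Largest `min(n1, n2)` for which the exact distribution
#'   is used (default 20).
#' @return A [stat_result()] with `statistic_name = "U"`.
#' @export
mann_whitney <- function(x, y, exact_max_n = 20) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && min(n1, n2) <= exact_max_n) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    return(stat_result("U", U, c(n1, n2), p, "Mann-Whitney (exact)"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sig2 <- n1 * n2 / 12 *
    (n1 + n2 + 1 - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  stat_result("U", U, c(n1, n2), min(1, 2 * stats::pnorm(-abs(z))),
              "Mann-Whitney (normal approx.)")
}

#' Shapiro-Wilk normality test
#'
#' Normality screen used to choose between parametric and rank-based paired
#' comparisons. Wraps the standard approximation algorithm.
#'
#' @param x Numeric sample, `3 <= n <= 5000`, not constant.
#' @return A [stat_result()] with `statistic_name = "SW"`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  sw <- stats::shapiro.test(x)
  stat_result("SW", unname(sw$statistic), n, sw$p.value, "Shapiro-Wilk")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q values, monotone and capped at 1, returned in the
#' input order.
#'
#' @param p Vector of raw P values in `[0, 1]`.
#' @return Vector of adjusted q values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
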