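test_that("permutation t test: identities, bounds, classical agreement", {
  x <- c(1, 2, 3, 4, 5)
  r <- perm_ttest(x, x, n_perm = 500, seed = 1)
  expect_gt(r$p_raw, 0.9)

  # swapping samples flips the sign, P unchanged (same seed)
  y <- c(2.5, 3.1, 4.8, 5.2, 6.0)
  r1 <- perm_ttest(x, y, n_perm = 2000, seed = 3)
  r2 <- perm_ttest(y, x, n_perm = 2000, seed = 3)
  expect_equal(r1$value, -r2$value)
  expect_equal(r1$p_raw, r2$p_raw)

  # add-one lower bound: P can never be smaller than 1/(n_perm + 1)
  a <- 1:5; b <- 101:105
  r <- perm_ttest(a, b, n_perm = 200, seed = 2)
  expect_gte(r$p_raw, 1 / 201)
  expect_lt(r$p_raw, 0.05)

  # identical constant samples: degenerate, P = 1
  r <- perm_ttest(rep(2, 4), rep(2, 4), n_perm = 100, seed = 1)
  expect_true(r$degenerate)
  expect_equal(r$p_raw, 1)

  # observed pooled t matches the classical statistic
  ct <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(r1$value, unname(ct$statistic))
  # and the permutation P approaches the classical P for normal-ish data
  set.seed(5)
  xx <- rnorm(20); yy <- rnorm(20, 0.3)
  rp <- perm_ttest(xx, yy, n_perm = 1e5, seed = 6)
  cp <- stats::t.test(xx, yy, var.equal = TRUE)$p.value
  expect_lt(abs(rp$p_raw - cp), 0.01)
})

test_that("permutation ANOVA: observed F classical, degenerate convention", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
  r <- perm_oneway_anova(g, n_perm = 1000, seed = 1)
  aovF <- unname(summary(stats::aov(
    v ~ grp, data.frame(v = unlist(g),
                        grp = factor(rep(1:3, each = 3)))))[[1]]$`F value`[1])
  expect_equal(r$value, aovF)
  expect_equal(unname(r$df), c(2, 6))
  expect_gte(r$p_raw, 1 / 1001)

  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(perm_oneway_anova(same, n_perm = 500, seed = 1)$p_raw, 0.9)

  const <- list(rep(1, 3), rep(1, 3))
  rc <- perm_oneway_anova(const, n_perm = 100, seed = 1)
  expect_true(rc$degenerate)
  expect_equal(rc$p_raw, 1)
  expect_error(perm_oneway_anova(list(1:3), 100, 1))
})

test_that("permutation tests hold their type-I error near 5%", {
  set.seed(11)
  rej_t <- vapply(1:300, function(i) {
    x <- rnorm(8); y <- rnorm(8)
    perm_ttest(x, y, n_perm = 400, seed = i)$p_raw < 0.05
  }, logical(1))
  expect_gt(mean(rej_t), 0.025)
  expect_lt(mean(rej_t), 0.08)

  rej_F <- vapply(1:300, function(i) {
    g <- list(rnorm(6), rnorm(6), rnorm(6))
    perm_oneway_anova(g, n_perm = 400, seed = i)$p_raw < 0.05
  }, logical(1))
  expect_gt(mean(rej_F), 0.025)
  expect_lt(mean(rej_F), 0.08)
})

test_that("split-plot ANOVA reproduces zero-effect identities", {
  # identical group means at every time: F_group = 0
  tab <- rbind(
    data.frame(subject = "s1", group = "a", time = 1:3, value = c(1, 2, 3)),
    data.frame(subject = "s2", group = "a", time = 1:3, value = c(3, 2, 1)),
    data.frame(subject = "s3", group = "b", time = 1:3, value = c(2, 3, 1)),
    data.frame(subject = "s4", group = "b", time = 1:3, value = c(2, 1, 3)))
  r <- mixed_rm_anova(tab)
  expect_equal(r$F[r$effect == "group"], 0)

  # values constant per subject: SS_time = SS_interaction = 0
  tab2 <- do.call(rbind, lapply(1:4, function(s)
    data.frame(subject = paste0("s", s), group = c("a", "a", "b", "b")[s],
               time = 1:4, value = s)))
  r2 <- mixed_rm_anova(tab2)
  expect_equal(r2$SS[r2$effect == "time"], 0)
  expect_equal(r2$SS[r2$effect == "group_x_time"], 0)
})

test_that("split-plot sums of squares match the projection oracle and aov", {
  set.seed(42)
  for (rep in 1:12) {
    k <- sample(2:4, 1); npg <- sample(2:5, 1); a <- sample(2:6, 1)
    tab <- random_long_table(k, npg, a)
    r <- mixed_rm_anova(tab)
    orc <- oracle_splitplot_ss(tab)
    # oracle returns per-observation projections; scale group/subject/time
    expect_equal(r$SS, unname(orc[r$effect]), tolerance = 1e-10)
    # additivity to 10 significant digits
    expect_equal(sum(r$SS), sum((tab$value - mean(tab$value))^2),
                 tolerance = 1e-10)
    # cross-check F and P against aov with an Error stratum
    tab$subject <- factor(tab$subject); tab$group <- factor(tab$group)
    tab$time <- factor(tab$time)
    av <- summary(stats::aov(value ~ group * time + Error(subject),
                             data = tab))
    Fa <- av[["Error: subject"]][[1]]$`F value`[1]
    Fw <- av[["Error: Within"]][[1]]$`F value`[1:2]
    expect_equal(r$F[r$effect == "group"], Fa, tolerance = 1e-8)
    expect_equal(r$F[r$effect == "time"], Fw[1], tolerance = 1e-8)
    expect_equal(r$F[r$effect == "group_x_time"], Fw[2], tolerance = 1e-8)
  }
  bad <- random_long_table(2, 3, 4)[-1, ]
  expect_error(mixed_rm_anova(bad), "unbalanced")
})

test_that("summary-statistic t tests reproduce printed open-field results", {
  # number of centre entries: ctrl 3.4 +/- 2.702 vs treated 7.8 +/- 3.114
  r1 <- pooled_t_summary(3.4, 2.702, 5, 7.8, 3.114, 5)
  expect_equal(abs(r1$value), 2.386, tolerance = 5e-4)
  expect_equal(r1$df, 8)
  expect_equal(r1$p_raw, 0.0441, tolerance = 5e-3)

  # mean entry duration: 8.482 +/- 4.258 vs 2.846 +/- 1.36 (Welch)
  r2 <- welch_t_summary(8.482, 4.258, 5, 2.846, 1.36, 5)
  expect_equal(abs(r2$value), 2.819, tolerance = 5e-4)
  expect_equal(r2$df, 4.807, tolerance = 5e-4)
  expect_equal(r2$p_raw, 0.0388, tolerance = 5e-3)

  # locomotor activity: 11961 +/- 7760 vs 22119 +/- 11181 (Welch)
  r3 <- welch_t_summary(11961, 7760, 5, 22119, 11181, 5)
  expect_equal(abs(r3$value), 1.669, tolerance = 5e-4)
  expect_equal(r3$df, 7.128, tolerance = 5e-4)
  expect_equal(r3$p_raw, 0.1383, tolerance = 5e-3)

  # equal summaries: t = 0, P = 1
  r0 <- pooled_t_summary(5, 1, 5, 5, 1, 5)
  expect_equal(r0$value, 0)
  expect_equal(r0$p_raw, 1)
  rw <- welch_t_summary(5, 0, 5, 5, 0, 5)
  expect_true(rw$degenerate)
})

test_that("paired t matches the difference-vector t test and flags degeneracy", {
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  r <- paired_t(x, y)
  ct <- stats::t.test(x, y, paired = TRUE)
  expect_equal(r$value, unname(ct$statistic))
  expect_equal(r$p_raw, ct$p.value)
  expect_equal(r$df, 9)

  same <- paired_t(x, x)
  expect_true(same$degenerate)
  expect_equal(same$value, 0)
  shift <- paired_t(x, x + 1)
  expect_true(shift$degenerate)
  expect_true(is.infinite(shift$value))
})

test_that("signed-rank test is exact for small untied samples", {
  # n = 5, all differences positive: W = 15, P = 2/32
  x <- c(2, 4, 6, 8, 10); y <- c(1, 2, 3, 4, 5)
  r <- wilcoxon_signed_rank(x, y)
  expect_equal(r$value, 15)
  expect_equal(r$p_raw, 2 / 32)

  # sign flip: W -> n(n+1)/2 - W, same P
  rf <- wilcoxon_signed_rank(y, x)
  expect_equal(rf$value, 0)
  expect_equal(rf$p_raw, r$p_raw)

  # n = 8 random data vs full 2^8 enumeration oracle
  set.seed(14)
  for (i in 1:5) {
    d <- round(rnorm(8, 0.3), 3)
    r <- wilcoxon_signed_rank(d)
    expect_equal(r$p_raw, oracle_signrank_p(d))
    wt <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(r$p_raw, wt$p.value)
  }
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
})

test_that("Mann-Whitney is exact for small untied samples", {
  # complete separation at n = 5/5: U = 0, P = 2/252
  lo <- c(1, 2, 3, 4, 5); hi <- c(6, 7, 8, 9, 10)
  r <- mann_whitney(lo, hi)
  expect_equal(r$value, 0)
  expect_equal(r$p_raw, 2 / 252)

  # swap: U -> n1 n2 - U, same P
  rs <- mann_whitney(hi, lo)
  expect_equal(rs$value, 25)
  expect_equal(rs$p_raw, r$p_raw)

  # random tie-free cases vs the full C(n1+n2, n1) enumeration oracle
  set.seed(8)
  for (i in 1:5) {
    x <- round(rnorm(5), 3); y <- round(rnorm(4, 0.5), 3)
    r <- mann_whitney(x, y)
    expect_equal(r$p_raw, oracle_mannwhitney_p(x, y))
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(r$p_raw, wt$p.value)
  }
})

test_that("normality screen behaves across sample shapes", {
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "n")
  # heavily skewed samples are rejected far above the 5% rate
  set.seed(21)
  rej <- vapply(1:200, function(i)
    shapiro_wilk(rexp(50))$p_raw < 0.05, logical(1))
  expect_gt(mean(rej), 0.5)
  # normal samples give roughly uniform P (coarse two-bin check)
  p <- vapply(1:200, function(i) shapiro_wilk(rnorm(30))$p_raw, numeric(1))
  expect_gt(mean(p < 0.5), 0.35)
  expect_lt(mean(p < 0.5), 0.65)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.05 * 4 / 3, 0.5))
  p <- c(0.4, 0.01, 0.9, 0.02)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # FDR control under the global null: any q < 0.05 in ~5% of replicates
  set.seed(9)
  any_hit <- vapply(1:400, function(i)
    any(bh_fdr(runif(60)) < 0.05), logical(1))
  expect_lt(mean(any_hit), 0.10)
  expect_gt(mean(any_hit), 0.01)
})
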