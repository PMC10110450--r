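# Independent oracles used across the suite. Each deliberately recomputes
# its quantity by the most literal method available (double loops, full
# enumeration, per-sample counting) so it shares no code with the
# implementation it checks.

# lagged co-occurrence by explicit double loop (positive lag = partner leads)
oracle_profile <- function(s, p, max_lag) {
  T_ <- length(s)
  lags <- -max_lag:max_lag
  prob <- sapply(lags, function(tau) {
    acc <- 0L; nv <- 0L
    for (t in seq_len(T_)) {
      ts <- t + tau
      if (ts >= 1 && ts <= T_) {
        acc <- acc + s[ts] * p[t]
        nv <- nv + 1L
      }
    }
    acc / nv
  })
  data.frame(lag_s = lags, prob = prob)
}

# per-sample window freezing oracle at the series' sampling rate
oracle_window_pct <- function(series, from, to) {
  v <- as_binary(series)
  t_mid <- (seq_along(v) - 1) / series$fs
  sel <- t_mid >= from & t_mid < to
  100 * sum(v[sel]) / sum(sel)
}

# exact two-sided signed-rank P by enumerating all 2^n sign patterns
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  # two-sided: patterns at least as extreme (by distance from the mean)
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

# exact two-sided Mann-Whitney P by enumerating all C(n1+n2, n1) splits
oracle_mannwhitney_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  U_of <- function(idx) {
    xx <- z[idx]; yy <- z[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  U_obs <- U_of(seq_len(n1))
  mu <- n1 * n2 / 2
  splits <- utils::combn(n1 + n2, n1)
  U_all <- apply(splits, 2, U_of)
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# split-plot sums of squares by explicit cell-mean projections
oracle_splitplot_ss <- function(df) {
  df$subject <- factor(df$subject); df$group <- factor(df$group)
  df$time <- factor(df$time)
  grand <- mean(df$value)
  mg <- tapply(df$value, df$group, mean)
  ms <- tapply(df$value, df$subject, mean)
  mt <- tapply(df$value, df$time, mean)
  mgt <- tapply(df$value, list(df$group, df$time), mean)
  sg <- tapply(as.character(df$group), df$subject, function(v) v[1])
  e_group <- mg[df$group] - grand
  e_subj <- ms[df$subject] - mg[sg[df$subject]]
  e_time <- mt[df$time] - grand
  e_int <- mgt[cbind(df$group, df$time)] - mg[df$group] - mt[df$time] + grand
  e_res <- df$value - ms[df$subject] - mgt[cbind(df$group, df$time)] +
    mg[df$group]
  c(group = sum(e_group^2), subject_within_group = sum(e_subj^2),
    time = sum(e_time^2), group_x_time = sum(e_int^2),
    residual = sum(e_res^2))
}

# random balanced long table for split-plot tests
random_long_table <- function(k = 3, n_per_group = 4, a = 5) {
  subj <- 0
  do.call(rbind, lapply(seq_len(k), function(g) {
    do.call(rbind, lapply(seq_len(n_per_group), function(i) {
      subj <<- subj + 1
      data.frame(subject = paste0("s", subj), group = paste0("g", g),
                 time = seq_len(a),
                 value = rnorm(a, mean = g + 0.5 * seq_len(a)))
    }))
  }))
}

# simulate one dyad on a CS-free stationary session and return 1-Hz vectors
sim_dyad_1hz <- function(len_s, kappa = 0, delta = 0, seed = 1,
                         p_on = 0.005, p_off = 0.015) {
  sc <- make_schedule("cage_exposure",
                      overrides = list(session_length_s = len_s,
                                       habituation_s = 0))
  d <- simulate_dyad(sc, dyad_sim_config(
    p_on_base = p_on, p_off_base = p_off, coupling = kappa,
    lag_s = delta, seed = seed))
  list(s = downsample_1hz(d$subject), p = downsample_1hz(d$partner))
}
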