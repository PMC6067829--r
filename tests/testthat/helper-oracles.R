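# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: naive per-trial loops, exhaustive
# lattice searches and exhaustive permutation enumerations.

# Per-trial loop log-likelihood (no vectorization, no clipping shortcuts).
naive_log_likelihood <- function(data, lambda, mu, c_bias) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    sug <- 0.5 * data$gain[i] - 0.5 * data$loss[i] * lambda
    p <- 1 / (1 + exp(-(mu * sug + c_bias)))
    p <- min(max(p, 1e-12), 1 - 1e-12)
    total <- total + if (data$accepted[i]) log(p) else log(1 - p)
  }
  total
}

# Lattice maximum-likelihood search on a 0.05-step grid. The gambling bias
# c is always searched exhaustively over its full lattice (it trades off
# strongly against mu * lambda), while lambda and mu are refined
# coarse-to-fine down to the 0.05 step.
grid_search_ml <- function(data, step = 0.05) {
  g <- data$gain
  l <- data$loss
  y <- as.numeric(data$accepted)
  c_grid <- seq(-10, 10, step)
  ll_grid <- function(lam_grid, mu_grid) {
    best <- c(-Inf, NA, NA, NA)
    for (lam in lam_grid) {
      s <- 0.5 * g - 0.5 * l * lam
      a <- outer(s, mu_grid)
      for (ci in c_grid) {
        eta <- a + ci
        ll <- colSums(y * eta - log1p(exp(eta)))
        j <- which.max(ll)
        if (ll[j] > best[1]) best <- c(ll[j], lam, mu_grid[j], ci)
      }
    }
    best
  }
  win <- function(x, w, s) seq(max(0, x - w), min(10, x + w), s)
  b <- ll_grid(seq(0, 10, 0.5), seq(0, 10, 0.5))
  b <- ll_grid(win(b[2], 1, 0.1), win(b[3], 1, 0.1))
  b <- ll_grid(win(b[2], 0.15, step), win(b[3], 0.15, step))
  c(lambda = b[2], mu = b[3], c = b[4], loglik = b[1])
}

# Naive loop version of the group moment update.
naive_group_moments <- function(fits) {
  k <- length(fits[[1]]$theta)
  n <- length(fits)
  m <- rep(0, k)
  s2 <- rep(0, k)
  for (f in fits) {
    m <- m + f$theta / n
    s2 <- s2 + (f$theta^2 + diag(solve(f$hessian))) / n
  }
  list(mean = m, var = pmax(s2 - m^2, 1e-3))
}

# Naive term-by-term NLME.
naive_nlme <- function(fits, prior, m, n_units) {
  total <- 0
  for (f in fits) {
    total <- total - f$log_lik
    for (j in names(f$theta)) {
      if (is.finite(prior$var[j])) {
        total <- total - dnorm(f$theta[j], prior$mean[j], sqrt(prior$var[j]),
                               log = TRUE)
      }
    }
    total <- total + 0.5 * log(det(f$hessian))
  }
  unname(total - 0.5 * m * n_units * log(2 * pi) + m * log(n_units))
}

# Exact two-tailed signed-rank p by enumerating all 2^n sign assignments,
# with R's doubling convention.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-tailed Mann-Whitney p by enumerating all choose(na+nb, na)
# labelings.
enumerate_mann_whitney_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# From-scratch sums-of-squares split-plot ANOVA for a balanced two-group,
# two-session design. Returns F for group, session and interaction.
ss_mixed_anova <- function(data) {
  gm <- mean(data$value)
  subj <- unique(data$subject_id)
  subj_mean <- tapply(data$value, data$subject_id, mean)
  subj_group <- tapply(as.character(data$group), data$subject_id, `[`, 1)
  grp_mean <- tapply(data$value, data$group, mean)
  ses_mean <- tapply(data$value, data$session, mean)
  cell_mean <- tapply(data$value, list(data$group, data$session), mean)
  n_g <- table(subj_group)

  ss_between_subj <- 2 * sum((subj_mean - gm)^2)
  ss_group <- 2 * sum(n_g * (grp_mean[names(n_g)] - gm)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_session <- length(subj) * sum((ses_mean - gm)^2)
  ss_inter <- 0
  for (g in rownames(cell_mean)) {
    for (s in colnames(cell_mean)) {
      ss_inter <- ss_inter + n_g[g] *
        (cell_mean[g, s] - grp_mean[g] - ses_mean[s] + gm)^2
    }
  }
  ss_total <- sum((data$value - gm)^2)
  ss_within_err <- ss_total - ss_between_subj - ss_session - ss_inter

  df_group <- length(n_g) - 1
  df_subj_err <- length(subj) - length(n_g)
  df_session <- 1
  df_inter <- df_group
  df_within_err <- df_subj_err

  list(
    F_group = (ss_group / df_group) / (ss_subj_err / df_subj_err),
    F_session = (ss_session / df_session) / (ss_within_err / df_within_err),
    F_interaction = (ss_inter / df_inter) / (ss_within_err / df_within_err)
  )
}
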