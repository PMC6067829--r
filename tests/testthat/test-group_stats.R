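test_that("normality routing separates normal from heavy-tailed samples", {
  n_seeds <- 40
  heavy <- sum(vapply(seq_len(n_seeds), function(s) {
    withr::with_seed(s, route_by_normality(rt(200, df = 2))) == "nonparametric"
  }, TRUE))
  expect_gte(heavy, 0.9 * n_seeds)
  normal <- sum(vapply(seq_len(n_seeds), function(s) {
    withr::with_seed(1000 + s, route_by_normality(rnorm(200))) == "parametric"
  }, TRUE))
  # the Shapiro-Wilk level is 5%, so ~95% of normal samples route parametric
  expect_gte(normal, 0.85 * n_seeds)
  expect_warning(out <- route_by_normality(rep(1, 10) + 1e-12 * c(1, rep(0, 9))),
                 "constant")
  expect_equal(out, "nonparametric")
})

test_that("signed-rank test matches exhaustive enumeration at small n", {
  withr::with_seed(80, {
    for (rep in 1:8) {
      n <- sample(5:9, 1)
      x <- round(rnorm(n, 0.3), 2)
      y <- round(rnorm(n), 2)
      d <- x - y
      if (any(d == 0) || any(duplicated(abs(d[d != 0])))) next
      got <- wilcoxon_signed_rank(x, y)
      expect_equal(got$p, enumerate_signed_rank_p(d), tolerance = 1e-12)
    }
  })
})

test_that("signed-rank edge cases behave", {
  x <- rnorm(22, 0, 0.2)
  expect_lt(wilcoxon_signed_rank(x + 1, x)$p, 0.001)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
  # large-n branch reports a standardized z
  withr::with_seed(81, {
    a <- rnorm(40)
    b <- a + rnorm(40, 0.5)
  })
  out <- wilcoxon_signed_rank(b, a)
  expect_false(is.na(out$z))
  expect_equal(out$p, 2 * pnorm(-abs(out$z)))
})

test_that("Mann-Whitney matches exhaustive labeling enumeration at small n", {
  withr::with_seed(82, {
    for (rep in 1:8) {
      a <- round(rnorm(5, 0.5), 2)
      b <- round(rnorm(5), 2)
      if (any(duplicated(c(a, b)))) next
      got <- mann_whitney_u(a, b)
      expect_equal(got$p, enumerate_mann_whitney_p(a, b), tolerance = 1e-12)
    }
  })
  # full separation puts U at an extreme
  expect_equal(mann_whitney_u(1:5, 11:15)$statistic, 0)
  expect_equal(mann_whitney_u(11:15, 1:5)$statistic, 25)
  # identical groups with midranks sit at the null centre
  out <- mann_whitney_u(rep(1:3, 4), rep(1:3, 4))
  expect_equal(out$statistic, 12 * 12 / 2)
  expect_gt(out$p, 0.9)
})

test_that("mixed ANOVA agrees with a from-scratch sums-of-squares oracle", {
  make_table <- function(seed, n_per = 8, effects = c(0, 0, 0), noise = 1) {
    withr::with_seed(seed, {
      grid <- expand.grid(subject = seq_len(2 * n_per), session = c("OFF", "ON"))
      grid$group <- ifelse(grid$subject <= n_per, "A", "B")
      subj_re <- rnorm(2 * n_per, 0, 0.5)
      grid$value <- effects[1] * (grid$group == "B") +
        effects[2] * (grid$session == "ON") +
        effects[3] * (grid$group == "B") * (grid$session == "ON") +
        subj_re[grid$subject] + rnorm(nrow(grid), 0, noise)
      names(grid)[1] <- "subject_id"
      grid
    })
  }
  for (seed in c(90, 91)) {
    tab <- make_table(seed, effects = c(0.5, 0.3, 0.4))
    got <- mixed_anova(tab)
    oracle <- ss_mixed_anova(tab)
    expect_equal(got$statistic[got$test == "mixed_anova_group"],
                 unname(oracle$F_group), tolerance = 1e-8)
    expect_equal(got$statistic[got$test == "mixed_anova_drug"],
                 unname(oracle$F_session), tolerance = 1e-8)
    expect_equal(got$statistic[got$test == "mixed_anova_interaction"],
                 unname(oracle$F_interaction), tolerance = 1e-8)
  }

  # constant response: all F = 0 (0/0 treated as NaN is not acceptable here,
  # so check a pure-interaction construction instead at near-zero noise)
  pure <- make_table(92, effects = c(0, 0, 0), noise = 1e-9)
  pure$value <- with(pure, ifelse((group == "B") == (session == "ON"), 1, -1) +
                      rnorm(nrow(pure), 0, 1e-9))
  got <- mixed_anova(pure)
  expect_gt(got$statistic[got$test == "mixed_anova_interaction"], 1e10)
  expect_lt(got$statistic[got$test == "mixed_anova_group"], 10)

  # incomplete cases rejected
  tab <- make_table(93)
  expect_error(mixed_anova(tab[-1, ]), "incomplete")
})

test_that("correlation p-values reproduce printed values from (rho, df)", {
  expect_equal(round(correlation_p(-0.384, 41), 3), 0.011)
  expect_equal(round(correlation_p(-0.348, 41), 3), 0.022)
  expect_equal(round(correlation_p(-0.592, 19), 3), 0.005)
})

test_that("correlation() computes coefficient and t-based p consistently", {
  withr::with_seed(94, {
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30)
  })
  got <- correlation(x, y, "pearson")
  ref <- cor.test(x, y)
  expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  gs <- correlation(x, y, "spearman")
  expect_equal(gs$statistic, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(gs$p, correlation_p(gs$statistic, 28))

  ident <- correlation(1:10, 1:10, "pearson")
  expect_equal(ident$statistic, 1)
  expect_equal(ident$p, 0)
  expect_error(correlation(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("Fisher r-to-z reproduces the printed group comparison", {
  out <- fisher_rz_compare(-0.592, 21, -0.021, 22)
  expect_equal(round(out$statistic, 2), -2.01)
  expect_lt(out$p, 0.05)
  expect_equal(fisher_rz_compare(0.4, 20, 0.4, 30)$statistic, 0)
  expect_equal(fisher_rz_compare(0.4, 20, 0.4, 30)$p, 1)
  a <- fisher_rz_compare(0.6, 25, 0.2, 30)
  b <- fisher_rz_compare(0.2, 30, 0.6, 25)
  expect_equal(a$statistic, -b$statistic)
})

test_that("bootstrap median SE is seeded and near the asymptotic value", {
  x <- rnorm(50)
  expect_equal(bootstrap_median_se(x, n_boot = 2000, seed = 5),
               bootstrap_median_se(x, n_boot = 2000, seed = 5))
  expect_equal(bootstrap_median_se(rep(3.2, 20), n_boot = 1000, seed = 6), 0)

  ses <- vapply(1:10, function(s) {
    x <- withr::with_seed(s, rnorm(100))
    bootstrap_median_se(x, n_boot = 1e4, seed = 100 + s)
  }, 0)
  asymptotic <- 1.2533 / sqrt(100)
  expect_lt(abs(mean(ses) - asymptotic) / asymptotic, 0.25)
})

test_that("drug-effect table applies the documented sign conventions", {
  params <- tibble::tibble(
    subject_id = rep(c("P1", "P2"), each = 2),
    group = "PD_dep_hist",
    session = rep(c("OFF", "ON"), 2),
    lambda = c(2, 1.5, 1, 1),
    mu = c(1, 1.2, 0.9, 0.8),
    c = c(-2, -0.5, -1, -1.2)
  )
  clinical <- tibble::tibble(subject_id = c("P1", "P2"),
                             group = "PD_dep_hist",
                             bdi_off = c(10, 4), bdi_on = c(6, 5))
  det <- drug_effect_table(params, clinical)
  expect_equal(det$d_lambda, c(-0.5, 0))
  expect_equal(det$d_c, c(1.5, -0.2))
  expect_equal(det$d_bdi, c(4, -1))  # positive = improvement ON

  expect_error(drug_effect_table(params[-1, ], clinical), "unmatched")
})
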