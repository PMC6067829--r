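#' Statistical battery for fitted parameters, acceptance rates and
#' clinical scores
#'
#' All tests are two-tailed. Normality (Shapiro--Wilk at alpha = 0.05)
#' routes a variable to the parametric or nonparametric branch;
#' within-subject contrasts use Wilcoxon signed-rank tests, between-group
#' contrasts Mann--Whitney tests, normally distributed outcomes a mixed
#' (split-plot) ANOVA with drug session as the within- and group as the
#' between-subject factor, and associations Pearson or Spearman
#' correlations with p-values from the t-approximation. Medians are
#' accompanied by bootstrap standard errors (SD of the median over 1e5
#' resamples). No multiple-comparison correction is applied.
#'
#' @name group_stats
NULL

stat_result <- function(test, statistic, statistic_name, p, df = NA_real_,
                        n = NA_integer_, ...) {
  tibble::tibble(test = test, statistic_name = statistic_name,
                 statistic = statistic, df = df, p = p, n = n, ...)
}

#' Route a variable to the parametric or nonparametric branch
#'
#' Shapiro--Wilk at `alpha`; p below `alpha` routes to the nonparametric
#' branch. Near-constant vectors (where the test is undefined) go to the
#' nonparametric branch with a warning.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Significance level of the normality test.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
route_by_normality <- function(values, alpha = 0.05) {
  stopifnot(length(values) >= 3)
  if (stats::sd(values) < sqrt(.Machine$double.eps)) {
    warning("near-constant values; routing to the nonparametric branch",
            call. = FALSE)
    return("nonparametric")
  }
  sw <- stats::shapiro.test(values)
  if (sw$p.value < alpha) "nonparametric" else "parametric"
}

#' Two-tailed Wilcoxon signed-rank test for paired values
#'
#' Zero differences are dropped. Exact enumeration when 25 or fewer
#' nonzero differences remain and their magnitudes are untied; otherwise
#' the continuity-corrected normal approximation (with tie correction),
#' whose standardized statistic `z` is reported alongside the signed-rank
#' statistic `V`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A one-row `StatResult` tibble.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- stats::wilcox.test(d, exact = TRUE)$p.value
    z <- NA_real_
  } else {
    mu_v <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma_v <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                      sum(tie_tab^3 - tie_tab) / 48)
    z <- (v - mu_v - sign(v - mu_v) * 0.5) / sigma_v
    p <- 2 * stats::pnorm(-abs(z))
  }
  stat_result("wilcoxon_signed_rank", v, "V", p = min(1, p), n = n, z = z)
}

#' Two-tailed Mann--Whitney U test
#'
#' Exact when both groups have 25 or fewer observations and there are no
#' ties; otherwise the continuity-corrected normal approximation with tie
#' correction. `U` is reported for the first group.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A one-row `StatResult` tibble.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  na <- length(group_a); nb <- length(group_b)
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(group_a, group_b)))
  if (na <= 25 && nb <= 25 && !ties) {
    p <- stats::wilcox.test(group_a, group_b, exact = TRUE)$p.value
    z <- NA_real_
  } else {
    mu_u <- na * nb / 2
    ntot <- na + nb
    tie_tab <- table(c(group_a, group_b))
    sigma_u <- sqrt(na * nb / 12 *
                      (ntot + 1 - sum(tie_tab^3 - tie_tab) / (ntot * (ntot - 1))))
    z <- (u - mu_u - sign(u - mu_u) * 0.5) / sigma_u
    p <- 2 * stats::pnorm(-abs(z))
  }
  stat_result("mann_whitney_u", u, "U", p = min(1, p), n = na + nb,
              n_a = na, n_b = nb, z = z)
}

#' Mixed (split-plot) ANOVA with one within- and one between-subject factor
#'
#' Fits `value ~ group * session` with subjects as whole plots: the Group
#' effect is tested against the between-subject error and the Drug
#' (session) and Group x Drug effects against the within-subject error.
#' Requires complete cases (every subject observed in both sessions).
#'
#' @param data Data frame with columns `subject_id`, `group` (2 levels),
#'   `session` (2 levels) and `value`.
#' @return A three-row `StatResult` tibble (Group, Drug, Group x Drug) with
#'   `F`, numerator/denominator dfs and p.
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("subject_id", "group", "session", "value") %in% names(data)))
  tab <- table(data$subject_id, data$session)
  if (any(tab != 1)) stop("incomplete cases: each subject needs exactly one value per session")
  data$subject_id <- factor(data$subject_id)
  data$group <- factor(data$group)
  data$session <- factor(data$session)
  fit <- stats::aov(value ~ group * session + Error(subject_id),
                    data = data)
  s <- summary(fit)
  between <- s[["Error: subject_id"]][[1]]
  within <- s[["Error: Within"]][[1]]
  get_row <- function(tbl, name) {
    i <- which(trimws(rownames(tbl)) == name)
    c(F = tbl[i, "F value"], df1 = tbl[i, "Df"],
      df2 = tbl[which(trimws(rownames(tbl)) == "Residuals"), "Df"],
      p = tbl[i, "Pr(>F)"])
  }
  g <- get_row(between, "group")
  d <- get_row(within, "session")
  gd <- get_row(within, "group:session")
  tibble::tibble(
    test = c("mixed_anova_group", "mixed_anova_drug", "mixed_anova_interaction"),
    statistic_name = "F",
    statistic = unname(c(g["F"], d["F"], gd["F"])),
    df1 = unname(c(g["df1"], d["df1"], gd["df1"])),
    df2 = unname(c(g["df2"], d["df2"], gd["df2"])),
    p = unname(c(g["p"], d["p"], gd["p"])),
    n = length(unique(data$subject_id))
  )
}

#' Two-tailed p-value of a correlation via the t-approximation
#'
#' `t = r * sqrt(df / (1 - r^2))` referred to a t distribution with
#' `df = n - 2` degrees of freedom; used for both Pearson's r and
#' Spearman's rho.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param df Degrees of freedom (`n - 2`).
#' @return The two-tailed p-value.
#' @export
correlation_p <- function(r, df) {
  stopifnot(abs(r) < 1, df >= 1)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' Two-tailed Pearson or Spearman correlation
#'
#' Spearman uses midranks; both methods take their p-value from the
#' t-approximation with `n - 2` degrees of freedom (see
#' [correlation_p()]).
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row `StatResult` tibble with the coefficient, df and p.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y, method = method)
  n <- length(x)
  p <- if (abs(r) < 1) correlation_p(r, n - 2) else 0
  stat_result(paste0("correlation_", method), r,
              if (method == "pearson") "r" else "rho",
              p = p, df = n - 2, n = n)
}

#' Compare two independent correlations by Fisher's r-to-z transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to
#' the standard normal, two-tailed.
#'
#' @param r1,r2 Correlation coefficients (`|r| < 1`).
#' @param n1,n2 Sample sizes (> 3).
#' @return A one-row `StatResult` tibble with `z` and p.
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  stat_result("fisher_rz", z, "z", p = 2 * stats::pnorm(-abs(z)),
              n = n1 + n2, n_a = n1, n_b = n2)
}

#' Bootstrap standard error of the median
#'
#' Resamples the vector with replacement `n_boot` times and returns the
#' standard deviation of the resampled medians.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param n_boot Number of bootstrap resamples (1e5 by default).
#' @param seed Integer seed.
#' @return The bootstrap SE (a single number).
#' @export
bootstrap_median_se <- function(values, n_boot = 1e5, seed = 1) {
  stopifnot(length(values) >= 2)
  n <- length(values)
  with_local_seed(seed, {
    m <- matrix(sample(values, n * n_boot, replace = TRUE), nrow = n)
    stats::sd(apply(m, 2, stats::median))
  })
}

#' Per-subject drug-effect table
#'
#' Joins the ON-minus-OFF parameter differences with the clinical
#' covariates using the sign conventions of the correlational analyses:
#' `d_lambda = lambda_ON - lambda_OFF` (negative = reduced loss aversion
#' ON), `d_c = c_ON - c_OFF`, and `d_bdi = BDI_OFF - BDI_ON` (positive =
#' depression improvement ON).
#'
#' @param params Tidy parameter tibble (e.g. from [fit_parameters()]) with
#'   `subject_id`, `group`, `session`, `lambda`, `mu`, `c`; sessions `ON`
#'   and `OFF` must both be present for every subject included.
#' @param clinical Clinical tibble with `subject_id`, `bdi_off`, `bdi_on`
#'   (and any further covariates, carried through).
#' @return Tibble with one row per subject: `d_lambda`, `d_mu`, `d_c`,
#'   `d_bdi`, plus the clinical columns.
#' @export
drug_effect_table <- function(params, clinical) {
  pp <- params[params$session %in% c("ON", "OFF"), ]
  wide <- tidyr::pivot_wider(
    pp[, c("subject_id", "group", "session", "lambda", "mu", "c")],
    names_from = "session", values_from = c("lambda", "mu", "c")
  )
  if (anyNA(wide[, c("lambda_ON", "lambda_OFF")])) {
    stop("unmatched subject: both ON and OFF sessions are required")
  }
  wide$d_lambda <- wide$lambda_ON - wide$lambda_OFF
  wide$d_mu <- wide$mu_ON - wide$mu_OFF
  wide$d_c <- wide$c_ON - wide$c_OFF
  out <- dplyr::left_join(wide, clinical, by = intersect(
    c("subject_id", "group"), names(clinical)
  ))
  out$d_bdi <- out$bdi_off - out$bdi_on
  out
}
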