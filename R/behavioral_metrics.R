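#' Model-free behavioural measures
#'
#' Screening of non-utility-maximizers, gamble acceptance rates, and
#' loss-sensitivity curves built from raw accept/reject counts.
#'
#' @name behavioral_metrics
NULL

# Unpenalized ML fit with the lower bound on mu relaxed to -10, so that
# sign-flipped (utility-minimizing) response patterns show up as negative
# inverse temperatures instead of piling up at mu = 0.
ml_fit_unbounded_mu <- function(data, n_starts = 5, seed = 1) {
  obj <- make_objective(data, flat_prior("full"), "full")
  b <- param_bounds("full", mu_lower = -10)
  starts <- list(c(lambda = 1, mu = 1, c = 0),
                 c(lambda = 1, mu = -1, c = 0))
  extra <- with_local_seed(seed, {
    matrix(stats::runif(3 * max(0, n_starts - 2), -1, 1), ncol = 3)
  })
  for (i in seq_len(nrow(extra))) {
    starts[[length(starts) + 1]] <- c(
      lambda = 1 + extra[i, 1], mu = 2 * extra[i, 2], c = 2 * extra[i, 3]
    )
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, fn = obj$nlp, gr = obj$grad, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("ML screening fit failed")
  stats::setNames(best$par, c("lambda", "mu", "c"))
}

#' Screen one subject-session for utility-maximizing behaviour
#'
#' A well-behaved subject accepts more gambles as gains grow and fewer as
#' losses grow. The screen fits the choice model by unpenalized maximum
#' likelihood with the inverse temperature free in `[-10, 10]` and
#' examines the acceptance trends in gain and loss (logistic regression).
#' A negative fitted `mu` together with a negative gain trend flags a
#' sign-flipped ("inverted") subject: such a response pattern maximizes
#' rather than minimizes expected losses. A random responder is flagged
#' when the acceptance rate lies in `[0.35, 0.65]` and a likelihood-ratio
#' test of the gain/loss logistic model against the coin-flip null is
#' non-significant at `random_alpha`: genuine utility maximizers sit
#' astronomically far from the coin-flip null at 169 trials, so a strict
#' level catches nearly all coin-flippers while essentially never
#' excluding value-driven subjects. All-accept or all-reject data are
#' retained with a warning, since trends are undefined there.
#'
#' @param data Choice tibble for one subject-session; at least 50 trials.
#' @param alpha Significance level reported for the per-trend Wald tests.
#' @param random_alpha Level of the randomness likelihood-ratio test.
#' @return A `screen_result` tibble row: identifiers, `gain_slope_sign`,
#'   `loss_slope_sign`, `ml_mu_unbounded`, `verdict` (`include`,
#'   `exclude_inverted` or `exclude_random`).
#' @export
screen_utility_maximizer <- function(data, alpha = 0.05, random_alpha = 0.01) {
  if (nrow(data) < 50) stop("need at least 50 trials to screen")
  acc_rate <- mean(data$accepted)
  res <- tibble::tibble(
    subject_id = data$subject_id[1],
    session = data$session[1],
    gain_slope_sign = "0",
    loss_slope_sign = "0",
    ml_mu_unbounded = NA_real_,
    acceptance_rate = acc_rate,
    verdict = "include"
  )
  if (acc_rate == 0 || acc_rate == 1) {
    warning("degenerate data (all ", if (acc_rate == 1) "accepted" else "rejected",
            "); trends undefined, subject retained", call. = FALSE)
    return(res)
  }

  theta <- ml_fit_unbounded_mu(data)
  fit <- suppressWarnings(
    stats::glm(accepted ~ gain + loss, family = stats::binomial(), data = data)
  )
  co <- summary(fit)$coefficients
  gain_b <- co["gain", "Estimate"]
  loss_b <- co["loss", "Estimate"]

  # LRT against the coin-flip null (logit 0 on every trial, 3 constrained
  # parameters: intercept, gain, loss)
  ll_null <- nrow(data) * log(0.5)
  lrt <- 2 * (as.numeric(stats::logLik(fit)) - ll_null)
  lrt_p <- stats::pchisq(max(0, lrt), df = 3, lower.tail = FALSE)

  res$gain_slope_sign <- if (gain_b > 0) "+" else if (gain_b < 0) "-" else "0"
  res$loss_slope_sign <- if (loss_b > 0) "+" else if (loss_b < 0) "-" else "0"
  res$ml_mu_unbounded <- unname(theta["mu"])

  # the randomness check comes first: a coin-flipper's noise-level trends
  # carry arbitrary signs, so the inverted rule must only see subjects whose
  # choices depart decisively from chance
  if (acc_rate >= 0.35 && acc_rate <= 0.65 && lrt_p >= random_alpha) {
    res$verdict <- "exclude_random"
  } else if (theta["mu"] < 0 && gain_b < 0) {
    res$verdict <- "exclude_inverted"
  }
  res
}

#' Screen every subject-session in a dataset
#'
#' @param data Choice tibble covering multiple subject-sessions.
#' @param alpha Significance level passed to [screen_utility_maximizer()].
#' @return Tibble of screen results, one row per subject-session.
#' @export
screen_dataset <- function(data, alpha = 0.05) {
  units <- split_units(data)
  dplyr::bind_rows(lapply(units, screen_utility_maximizer, alpha = alpha))
}

#' Proportion of accepted gambles per stratum
#'
#' The acceptance rate is a compound measure of risky choice: it rises
#' with the gambling bias, falls with loss aversion, and is insensitive to
#' trial order.
#'
#' @param data Choice tibble.
#' @param by Character vector of grouping columns (e.g. `c("group",
#'   "session")` or `c("subject_id", "session")`).
#' @return Tibble with the grouping columns, `n_trials` and `prop_accepted`.
#' @export
proportion_accepted <- function(data, by = c("group", "session")) {
  stopifnot(all(by %in% names(data)))
  out <- dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
    n_trials = dplyr::n(),
    prop_accepted = mean(accepted),
    .groups = "drop"
  )
  if (any(out$n_trials == 0)) stop("empty stratum")
  out
}

#' Loss-sensitivity curve from raw choices
#'
#' For each loss magnitude, all gains are pooled and the log ratio of
#' rejected to accepted gambles is computed with a Haldane--Anscombe +0.5
#' continuity correction, `log((R + 0.5) / (A + 0.5))`. The loss axis is
#' centred on the mid-level of the observed loss range ("relative loss"),
#' and a least-squares slope over levels summarizes loss sensitivity: a
#' steeper slope means rejection grows faster as potential losses rise.
#'
#' @param data Choice tibble for one group-session (or any pool of trials).
#' @return A `loss_sensitivity_curve` list: `curve` (tibble with `loss`,
#'   `rel_loss`, `n_rejected`, `n_accepted`, `log_ratio`) and `slope`
#'   (per euro of loss).
#' @export
loss_sensitivity_curve <- function(data) {
  counts <- dplyr::summarise(
    dplyr::group_by(data, loss),
    n_rejected = sum(!accepted),
    n_accepted = sum(accepted),
    .groups = "drop"
  )
  counts <- counts[order(counts$loss), ]
  mid <- (min(counts$loss) + max(counts$loss)) / 2
  counts$rel_loss <- counts$loss - mid
  counts$log_ratio <- log((counts$n_rejected + 0.5) / (counts$n_accepted + 0.5))
  slope <- unname(stats::coef(stats::lm(log_ratio ~ rel_loss, data = counts))[2])
  structure(list(curve = counts[, c("loss", "rel_loss", "n_rejected",
                                    "n_accepted", "log_ratio")],
                 slope = slope),
            class = "loss_sensitivity_curve")
}

#' Plot loss-sensitivity curves
#'
#' @param curves Named list of `loss_sensitivity_curve` objects (names used
#'   as panel labels).
#' @return A ggplot object.
#' @export
plot_loss_sensitivity <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- dplyr::bind_rows(
    lapply(curves, function(x) x$curve), .id = "stratum"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = rel_loss, y = log_ratio,
                                   colour = stratum)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "relative loss (euros from mid-level)",
                  y = "log(rejected / accepted)") +
    ggplot2::theme_minimal()
}
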