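#' Prospect-theory choice model for mixed gambles
#'
#' The subjective utility of a 50/50 mixed gamble is
#' \deqn{SUG = p_{gain} \cdot Gain - p_{loss} \cdot Loss \cdot \lambda}
#' with `Loss` the absolute loss magnitude and \eqn{\lambda \ge 0} the loss
#' aversion weight: \eqn{\lambda > 1} means losses loom larger than equally
#' sized gains, \eqn{\lambda = 1} is gain--loss neutrality. The value
#' function is linear and outcome probabilities enter unweighted (both fixed
#' at 0.5), a standard simplification over the narrow stake range of this
#' task.
#'
#' Acceptance follows a biased logistic (softmax) rule
#' \deqn{p(accept) = 1 / (1 + e^{-(\mu \cdot SUG + c)})}
#' where \eqn{\mu \ge 0} is the inverse temperature (choice consistency;
#' units 1/euro) and `c` a value-independent gambling bias: `c > 0` pushes
#' toward accepting gambles regardless of their value, `c < 0` away from
#' them. In the hierarchical fit parameters are box-constrained to
#' \eqn{\lambda \in [0,10]}, \eqn{\mu \in [0,10]}, \eqn{c \in [-10,10]}.
#'
#' @name choice_model
NULL

# Parameter box used by the hierarchical fit. The behavioural screen relaxes
# the lower mu bound (see screen_utility_maximizer).
param_bounds <- function(variant = c("full", "no_bias"), mu_lower = 0) {
  variant <- match.arg(variant)
  lower <- c(lambda = 0, mu = mu_lower, c = -10)
  upper <- c(lambda = 10, mu = 10, c = 10)
  if (variant == "no_bias") {
    lower <- lower[c("lambda", "mu")]
    upper <- upper[c("lambda", "mu")]
  }
  list(lower = lower, upper = upper)
}

free_params <- function(variant = c("full", "no_bias")) {
  variant <- match.arg(variant)
  if (variant == "full") c("lambda", "mu", "c") else c("lambda", "mu")
}

#' Subjective utility of a gamble
#'
#' @param gain Gain amount(s) in euros (positive).
#' @param loss Loss magnitude(s) in euros (positive).
#' @param lambda Loss-aversion weight, must be non-negative.
#' @return `0.5 * gain - 0.5 * loss * lambda`, in euros.
#' @examples
#' subjective_utility(30, 3, lambda = 1) # 13.5
#' @export
subjective_utility <- function(gain, loss, lambda) {
  stopifnot(length(lambda) == 1, is.finite(lambda))
  if (lambda < 0) stop("`lambda` must be non-negative")
  0.5 * gain - 0.5 * loss * lambda
}

#' Probability of accepting a gamble
#'
#' Logistic rule on the biased logit `mu * sug + c`. Strictly increasing in
#' `sug` for `mu > 0` and in `c` always.
#'
#' @param sug Subjective utility (euros).
#' @param mu Inverse temperature (1/euro).
#' @param c_bias Value-independent gambling bias (log-odds offset).
#' @return Acceptance probability in (0, 1).
#' @export
acceptance_probability <- function(sug, mu, c_bias) {
  stats::plogis(mu * sug + c_bias)
}

# Clamp probabilities away from 0/1 before taking logs; guards saturated
# parameter regions.
.p_clip <- 1e-12

clip_prob <- function(p) pmin(pmax(p, .p_clip), 1 - .p_clip)

#' Log-likelihood of one subject-session's choices
#'
#' Sum over trials of `log p` for accepted gambles and `log(1 - p)` for
#' rejected ones, with `p` from [acceptance_probability()]. Probabilities
#' are clamped to `[1e-12, 1 - 1e-12]` so the value stays finite at
#' saturated parameters.
#'
#' @param data Tibble/data.frame of one subject-session with columns `gain`,
#'   `loss`, `accepted` (logical or 0/1).
#' @param lambda,mu,c_bias Model parameters.
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(data, lambda, mu, c_bias = 0) {
  if (nrow(data) == 0) stop("empty choice dataset")
  sug <- subjective_utility(data$gain, data$loss, lambda)
  p <- clip_prob(acceptance_probability(sug, mu, c_bias))
  y <- as.logical(data$accepted)
  sum(log(ifelse(y, p, 1 - p)))
}

#' Simulate choices on a schedule
#'
#' One Bernoulli draw per trial with the model's acceptance probability;
#' seeded and reproducible.
#'
#' @param schedule Schedule from [build_schedule()] (or any table with
#'   `gain` and `loss` columns).
#' @param lambda,mu,c_bias Generating parameters.
#' @param seed Integer seed.
#' @param subject_id,group,session Identifiers stamped on the output rows.
#' @return A choice tibble with columns `subject_id`, `group`, `session`,
#'   `trial_index`, `gain`, `loss`, `accepted`.
#' @export
simulate_choices <- function(schedule, lambda, mu, c_bias, seed,
                             subject_id = "sim", group = "sim",
                             session = "single") {
  sug <- subjective_utility(schedule$gain, schedule$loss, lambda)
  p <- acceptance_probability(sug, mu, c_bias)
  acc <- with_local_seed(seed, stats::runif(length(p)) < p)
  tibble::tibble(
    subject_id = subject_id,
    group = group,
    session = session,
    trial_index = seq_along(p),
    gain = schedule$gain,
    loss = schedule$loss,
    accepted = as.logical(acc)
  )
}

#' Read/write trial-level choice data
#'
#' CSV with columns `subject_id, group, session, trial_index, gain, loss,
#' accepted` (`accepted` stored as 0/1).
#'
#' @param data Choice tibble.
#' @param path File path.
#' @return `read_choices_csv()` returns the choice tibble;
#'   `write_choices_csv()` returns `path` invisibly.
#' @export
write_choices_csv <- function(data, path) {
  out <- data
  out$accepted <- as.integer(out$accepted)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices_csv
#' @export
read_choices_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out$accepted <- as.logical(out$accepted)
  out
}
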