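#' Hierarchical empirical-Bayes estimation of choice-model parameters
#'
#' Each subject-session is one unit `n` with its own parameter vector
#' \eqn{\theta^n = (\lambda, \mu, c)} (or \eqn{(\lambda, \mu)} for the
#' reduced, no-bias variant). All units in the fitted pool share a normal
#' prior with diagonal covariance, whose mean \eqn{\Theta} and variance
#' \eqn{\Sigma} are estimated from the data themselves: the algorithm
#' alternates (E) per-unit MAP estimation under the current prior with a
#' Laplace approximation of each posterior, and (M) moment updates of
#' \eqn{\Theta} and \eqn{\Sigma} from the MAP values and posterior
#' variances, until the group moments stop changing. Treating each
#' subject-session as a unit lets ON and OFF parameters differ per subject
#' while regularizing all of them toward the common group distribution.
#'
#' @name hierarchical_fit
NULL

# ---- group prior -----------------------------------------------------------

.var_floor <- 1e-3

#' Construct a group prior
#'
#' @param mean Named numeric vector of prior means (names `lambda`, `mu`
#'   and, for the full variant, `c`).
#' @param var Named numeric vector of prior variances, same names. `Inf`
#'   marks an (improper) flat prior on that coordinate.
#' @return A `group_prior` list with elements `mean` and `var`.
#' @export
group_prior <- function(mean, var) {
  stopifnot(identical(names(mean), names(var)), all(var > 0))
  structure(list(mean = mean, var = var), class = "group_prior")
}

#' @rdname group_prior
#' @param variant Model variant, `"full"` or `"no_bias"`.
#' @export
flat_prior <- function(variant = c("full", "no_bias")) {
  par <- free_params(match.arg(variant))
  group_prior(
    mean = stats::setNames(rep(0, length(par)), par),
    var = stats::setNames(rep(Inf, length(par)), par)
  )
}

# Log prior density (diagonal normal, native parameter space). Flat
# coordinates (infinite variance) contribute zero.
log_prior_density <- function(theta, prior) {
  fin <- is.finite(prior$var)
  if (!any(fin)) return(0)
  sum(stats::dnorm(theta[fin], prior$mean[fin], sqrt(prior$var[fin]), log = TRUE))
}

# ---- likelihood derivatives ------------------------------------------------

# Negative log-posterior and its analytic gradient/Hessian in native space.
# theta is the free-parameter vector in variant order; for "no_bias" c = 0.
# The logit is eta_i = mu * S_i + c with S_i = 0.5 g_i - 0.5 l_i lambda, so
#   d eta/d lambda = -0.5 l_i mu,  d eta/d mu = S_i,  d eta/d c = 1,
# and the only nonzero second derivative of eta is d2/(d lambda d mu) =
# -0.5 l_i.
make_objective <- function(data, prior, variant) {
  g <- data$gain
  l <- data$loss
  y <- as.numeric(data$accepted)
  par <- free_params(variant)
  fin <- is.finite(prior$var)
  pm <- prior$mean
  pv <- prior$var

  unpack <- function(theta) {
    list(lambda = theta[1], mu = theta[2],
         c = if (variant == "full") theta[3] else 0)
  }

  nlp <- function(theta) {
    th <- unpack(theta)
    s <- 0.5 * g - 0.5 * l * th$lambda
    eta <- th$mu * s + th$c
    # log(1 + exp(eta)) computed stably
    log1pexp <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    ll <- sum(y * eta - log1pexp)
    lp <- if (any(fin)) {
      sum(stats::dnorm(theta[fin], pm[fin], sqrt(pv[fin]), log = TRUE))
    } else 0
    -(ll + lp)
  }

  grad <- function(theta) {
    th <- unpack(theta)
    s <- 0.5 * g - 0.5 * l * th$lambda
    eta <- th$mu * s + th$c
    p <- stats::plogis(eta)
    r <- y - p
    g_ll <- c(
      lambda = sum(r * (-0.5 * l * th$mu)),
      mu = sum(r * s),
      c = sum(r)
    )[par]
    g_lp <- rep(0, length(par))
    g_lp[fin] <- -(theta[fin] - pm[fin]) / pv[fin]
    -(g_ll + g_lp)
  }

  # Hessian of the NEGATIVE log-posterior at theta (the Laplace H_n).
  hess <- function(theta) {
    th <- unpack(theta)
    s <- 0.5 * g - 0.5 * l * th$lambda
    eta <- th$mu * s + th$c
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    r <- y - p
    d_lam <- -0.5 * l * th$mu
    d_mu <- s
    d_c <- rep(1, length(s))
    H_ll <- matrix(0, 3, 3, dimnames = list(free_params("full"), free_params("full")))
    H_ll["lambda", "lambda"] <- -sum(w * d_lam^2)
    H_ll["mu", "mu"] <- -sum(w * d_mu^2)
    H_ll["c", "c"] <- -sum(w)
    H_ll["lambda", "mu"] <- H_ll["mu", "lambda"] <-
      sum(r * (-0.5 * l)) - sum(w * d_lam * d_mu)
    H_ll["lambda", "c"] <- H_ll["c", "lambda"] <- -sum(w * d_lam)
    H_ll["mu", "c"] <- H_ll["c", "mu"] <- -sum(w * d_mu)
    H <- -H_ll[par, par, drop = FALSE]
    diag(H) <- diag(H) + ifelse(fin, 1 / pv, 0)
    H
  }

  list(nlp = nlp, grad = grad, hess = hess, par = par)
}

# ---- per-unit MAP ----------------------------------------------------------

#' MAP fit for one subject-session
#'
#' Maximizes `log p(D | theta) + log N(theta | Theta, Sigma)` over the box
#' \eqn{\lambda, \mu \in [0, 10]}, \eqn{c \in [-10, 10]} by L-BFGS-B with
#' analytic gradients, from multiple seeded starting points (the prior mean,
#' any supplied warm start, and random draws from the prior), keeping the
#' best optimum. The Hessian of the negative log-posterior at the optimum is
#' computed analytically and defines the Laplace approximation of the
#' posterior.
#'
#' @param data Choice tibble for a single subject-session.
#' @param prior A [group_prior()] over the variant's free parameters.
#' @param variant `"full"` (3 free parameters) or `"no_bias"` (`c` fixed at
#'   0, 2 free parameters).
#' @param n_starts Number of optimization starts (at least 5 by default).
#' @param seed Integer seed for the random starts.
#' @param warm_start Optional named vector used as an additional start.
#' @return A `subject_fit` list: `theta` (named MAP vector), `log_posterior`,
#'   `log_lik`, `hessian`, `converged`, `at_boundary`, plus the identifiers
#'   found in `data`.
#' @export
fit_map_individual <- function(data, prior, variant = c("full", "no_bias"),
                               n_starts = 5, seed = 1, warm_start = NULL) {
  variant <- match.arg(variant)
  obj <- make_objective(data, prior, variant)
  b <- param_bounds(variant)
  par <- obj$par

  starts <- list()
  mid <- ifelse(is.finite(prior$mean), prior$mean, 0)
  starts[[1]] <- pmin(pmax(mid, b$lower), b$upper)
  if (!is.null(warm_start)) starts[[length(starts) + 1]] <- warm_start[par]
  n_rand <- max(0, n_starts - length(starts))
  if (n_rand > 0) {
    sd0 <- ifelse(is.finite(prior$var), sqrt(prior$var), 1.5)
    draws <- with_local_seed(seed, {
      matrix(stats::rnorm(n_rand * length(par), mean = rep(starts[[1]], each = n_rand),
                          sd = rep(sd0, each = n_rand)), nrow = n_rand)
    })
    for (i in seq_len(n_rand)) {
      starts[[length(starts) + 1]] <-
        pmin(pmax(stats::setNames(draws[i, ], par), b$lower), b$upper)
    }
  }

  best <- NULL
  any_ok <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, fn = obj$nlp, gr = obj$grad, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    any_ok <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!any_ok) {
    stop("optimizer failed for unit ", data$subject_id[1], "/", data$session[1],
         " after ", length(starts), " starts")
  }

  theta <- stats::setNames(best$par, par)
  at_boundary <- any(theta - b$lower < 1e-3 | b$upper - theta < 1e-3)
  H <- obj$hess(theta)
  structure(list(
    subject_id = data$subject_id[1],
    group = data$group[1],
    session = data$session[1],
    theta = theta,
    log_posterior = -best$value,
    log_lik = log_likelihood(data, theta["lambda"], theta["mu"],
                             if (variant == "full") theta["c"] else 0),
    hessian = H,
    converged = best$convergence == 0,
    at_boundary = at_boundary,
    variant = variant
  ), class = "subject_fit")
}

# Finite-difference Hessian of the negative log-posterior; used as a
# cross-check of the analytic Hessian and as a fallback for singular ones.
fd_hessian <- function(data, prior, variant, theta) {
  obj <- make_objective(data, prior, variant)
  pracma::hessian(obj$nlp, theta)
}

# ---- group moment update ---------------------------------------------------

#' Update group mean and variance from Laplace posteriors
#'
#' The standard EM moment update for a random-effects normal with Laplace
#' posteriors: \eqn{\Theta' = mean_n(\theta^n)} and
#' \eqn{\Sigma' = mean_n(\theta^{n2} + diag(H_n^{-1})) - \Theta'^2},
#' floored elementwise at `1e-3`. A singular Hessian triggers a
#' pseudo-inverse fallback for that unit's posterior variance (with a
#' warning) rather than dropping the unit.
#'
#' @param fits List of `subject_fit` objects.
#' @return A [group_prior()].
#' @export
update_group_moments <- function(fits) {
  stopifnot(length(fits) >= 1)
  par <- names(fits[[1]]$theta)
  thetas <- do.call(rbind, lapply(fits, `[[`, "theta"))
  post_var <- do.call(rbind, lapply(fits, function(f) {
    v <- tryCatch(diag(solve(f$hessian)), error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v)) || any(v <= 0)) {
      warning("singular Hessian for unit ", f$subject_id, "/", f$session,
              "; using pseudo-inverse posterior variance", call. = FALSE)
      v <- diag(pracma::pinv(f$hessian))
      v[!is.finite(v) | v <= 0] <- .var_floor
    }
    v
  }))
  m <- colMeans(thetas)
  v <- colMeans(thetas^2 + post_var) - m^2
  v <- pmax(v, .var_floor)
  group_prior(stats::setNames(m, par), stats::setNames(v, par))
}

# ---- full iterative fit ----------------------------------------------------

split_units <- function(data) {
  key <- interaction(data$subject_id, data$session, drop = TRUE)
  split(data, key)
}

#' Fit the hierarchical model to a pool of subject-sessions
#'
#' Initializes with unpenalized per-unit maximum-likelihood fits, sets the
#' starting group moments to their 5%-trimmed mean and variance, then
#' alternates per-unit MAP fitting and group moment updates until the
#' largest absolute change in \eqn{\Theta} and \eqn{\Sigma} drops below
#' `tol` (or `max_iter` is reached, in which case `converged` is `FALSE`).
#' All units passed in share one prior.
#'
#' The `strategy` argument selects the unit pool: `"pooled"` uses every
#' subject-session in `data`; `"patients_only"` drops healthy controls
#' (group `"HC"`) and pools both patient groups and both drug sessions under
#' one prior; `"controls_plus_patients_per_session"` runs two separate fits,
#' each combining the controls' single session with the patients' OFF (resp.
#' ON) session, returned as a named list.
#'
#' @param data Choice tibble covering one or more subject-sessions.
#' @param variant `"full"` or `"no_bias"`.
#' @param strategy Unit-pool strategy; see Details.
#' @param tol Convergence tolerance on the group moments.
#' @param max_iter Maximum number of EM iterations.
#' @param n_starts Optimization starts per unit in the first iteration
#'   (later iterations warm-start from the previous MAP).
#' @param seed Integer seed for optimizer restarts.
#' @return A `hier_fit` list: `prior` (the converged [group_prior()]),
#'   `fits` (list of `subject_fit`), `trace` (tibble with per-iteration
#'   moments, objective and change), `converged`, `variant`, `n_units`.
#'   For the per-session strategy, a named list of two such objects
#'   (`OFF`, `ON`).
#' @export
fit_hierarchical <- function(data, variant = c("full", "no_bias"),
                             strategy = c("pooled", "patients_only",
                                          "controls_plus_patients_per_session"),
                             tol = 1e-4, max_iter = 500, n_starts = 5,
                             seed = 1) {
  variant <- match.arg(variant)
  strategy <- match.arg(strategy)

  if (strategy == "patients_only") {
    data <- data[data$group != "HC", , drop = FALSE]
    strategy <- "pooled"
  } else if (strategy == "controls_plus_patients_per_session") {
    out <- lapply(c(OFF = "OFF", ON = "ON"), function(ses) {
      pool <- data[data$session %in% c("single", ses), , drop = FALSE]
      fit_hierarchical(pool, variant = variant, strategy = "pooled",
                       tol = tol, max_iter = max_iter, n_starts = n_starts,
                       seed = seed)
    })
    return(out)
  }

  units <- split_units(data)
  stopifnot(length(units) >= 1, all(vapply(units, nrow, 1L) >= 1))
  par <- free_params(variant)

  # init: unpenalized ML per unit, robust moments
  fp <- flat_prior(variant)
  ml <- lapply(seq_along(units), function(i) {
    fit_map_individual(units[[i]], fp, variant, n_starts = n_starts,
                       seed = seed + i)
  })
  thetas <- do.call(rbind, lapply(ml, `[[`, "theta"))
  tm <- apply(thetas, 2, mean, trim = 0.05)
  tv <- pmax(apply(thetas, 2, trimmed_var, trim = 0.05), .var_floor)
  prior <- group_prior(stats::setNames(tm, par), stats::setNames(tv, par))

  fits <- ml
  trace <- list()
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fits <- lapply(seq_along(units), function(i) {
      fit_map_individual(units[[i]], prior, variant,
                         n_starts = max(2, ceiling(n_starts / 2)),
                         seed = seed + 1000 * iter + i,
                         warm_start = fits[[i]]$theta)
    })
    objective <- sum(vapply(fits, `[[`, 0, "log_posterior"))
    new_prior <- update_group_moments(fits)
    delta <- max(abs(new_prior$mean - prior$mean), abs(new_prior$var - prior$var))
    trace[[iter]] <- tibble::tibble(
      iteration = iter,
      parameter = par,
      theta_mean = unname(new_prior$mean),
      theta_var = unname(new_prior$var),
      objective = objective,
      delta = delta
    )
    prior <- new_prior
    if (delta < tol) { converged <- TRUE; break }
  }

  structure(list(
    prior = prior,
    fits = fits,
    trace = dplyr::bind_rows(trace),
    converged = converged,
    variant = variant,
    n_units = length(units)
  ), class = "hier_fit")
}

trimmed_var <- function(x, trim = 0.05) {
  if (length(x) < 2) return(.var_floor)
  if (trim > 0 && length(x) > 4) {
    q <- stats::quantile(x, c(trim, 1 - trim), names = FALSE)
    x <- x[x >= q[1] & x <= q[2]]
  }
  stats::var(x)
}

#' Report MAP estimates at or near the parameter bounds
#'
#' Laplace approximations are unreliable at box bounds, so units whose MAP
#' sits within `tol` of any bound are listed for inspection.
#'
#' @param fits List of `subject_fit` objects (or a `hier_fit`).
#' @param tol Distance to a bound that counts as "at" it.
#' @return Tibble with `subject_id`, `session`, `parameter`, `value`,
#'   `bound`; zero rows when all fits are interior.
#' @export
screen_boundary <- function(fits, tol = 1e-3) {
  if (inherits(fits, "hier_fit")) fits <- fits$fits
  rows <- lapply(fits, function(f) {
    b <- param_bounds(f$variant)
    th <- f$theta
    hit_lo <- th - b$lower < tol
    hit_hi <- b$upper - th < tol
    if (!any(hit_lo | hit_hi)) return(NULL)
    hit <- hit_lo | hit_hi
    tibble::tibble(
      subject_id = f$subject_id,
      session = f$session,
      parameter = names(th)[hit],
      value = unname(th[hit]),
      bound = unname(ifelse(hit_lo[hit], b$lower[hit], b$upper[hit]))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(subject_id = character(), session = character(),
                          parameter = character(), value = numeric(),
                          bound = numeric())
  }
  out
}

#' Tidy per-unit parameter estimates from a hierarchical fit
#'
#' @param fit A `hier_fit` object.
#' @return Tibble with one row per unit: identifiers, MAP `lambda`, `mu`,
#'   `c` (0 for the reduced variant), `log_lik`, `at_boundary`.
#' @export
fit_parameters <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  dplyr::bind_rows(lapply(fit$fits, function(f) {
    tibble::tibble(
      subject_id = f$subject_id,
      group = f$group,
      session = f$session,
      lambda = unname(f$theta["lambda"]),
      mu = unname(f$theta["mu"]),
      c = if ("c" %in% names(f$theta)) unname(f$theta["c"]) else 0,
      log_lik = f$log_lik,
      at_boundary = f$at_boundary
    )
  }))
}
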