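# Shared simulation helpers for the suite.

# Truncated-normal draw via the inverse CDF (kept independent of package
# internals).
rtn <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

# A pool of independent simulated subject-sessions with known parameters.
simulate_pool <- function(n_subjects, seed, lambda_mean = 1.3,
                          lambda_sd = 0.5, mu_mean = 1.0, mu_sd = 0.3,
                          c_mean = -1.5, c_sd = 1.2, session = "OFF",
                          group = "PD_nondep") {
  dats <- withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      lam <- rtn(1, lambda_mean, lambda_sd, 0, 10)
      mu <- rtn(1, mu_mean, mu_sd, 0, 10)
      cb <- if (c_sd == 0) c_mean else max(-10, min(10, rnorm(1, c_mean, c_sd)))
      d <- simulate_choices(build_schedule(seed * 1000 + i), lam, mu, cb,
                            seed = seed * 1000 + 500 + i,
                            subject_id = sprintf("S%03d", i),
                            group = group, session = session)
      attr(d, "truth") <- c(lambda = lam, mu = mu, c = cb)
      d
    })
  })
  list(
    data = dplyr::bind_rows(dats),
    truth = do.call(rbind, lapply(dats, attr, "truth"))
  )
}

# Minimal stub subject fit for closed-form evidence checks.
stub_fit <- function(theta, hessian, log_lik = 0, id = "S1", session = "OFF",
                     at_boundary = FALSE) {
  structure(list(subject_id = id, group = "PD_nondep", session = session,
                 theta = theta, log_posterior = log_lik, log_lik = log_lik,
                 hessian = hessian, converged = TRUE,
                 at_boundary = at_boundary,
                 variant = if (length(theta) == 3) "full" else "no_bias"),
            class = "subject_fit")
}

small_pipeline_config <- function(seed = 1) {
  pipeline_config(
    cohort = cohort_config(n_hc = 3, n_ndpd = 4, n_dpd = 4, seed = seed),
    seed = seed, tol = 1e-3, max_iter = 50, n_boot = 500
  )
}
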