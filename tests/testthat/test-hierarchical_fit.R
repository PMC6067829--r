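test_that("analytic Hessian of the negative log-posterior matches finite differences", {
  d <- simulate_choices(build_schedule(21), 1.5, 1, -1, seed = 22)
  prior <- group_prior(c(lambda = 1.3, mu = 1, c = -1.5),
                       c(lambda = 0.5, mu = 0.3, c = 1.2))
  f <- fit_map_individual(d, prior, "full", seed = 23)
  h_fd <- gambleb:::fd_hessian(d, prior, "full", f$theta)
  expect_lt(max(abs(f$hessian - h_fd) / (abs(h_fd) + 1)), 1e-4)
  expect_true(isSymmetric(f$hessian))
  expect_true(all(eigen(f$hessian, only.values = TRUE)$values > 0))
})

test_that("a flat prior reduces the MAP to maximum likelihood (grid oracle)", {
  d <- simulate_choices(build_schedule(24), 1.8, 1.2, -2, seed = 25)
  f_flat <- fit_map_individual(d, flat_prior("full"), "full", seed = 26)
  f_wide <- fit_map_individual(
    d, group_prior(c(lambda = 0, mu = 0, c = 0),
                   c(lambda = 1e6, mu = 1e6, c = 1e6)),
    "full", seed = 26
  )
  expect_equal(f_flat$theta, f_wide$theta, tolerance = 1e-3)
  o <- grid_search_ml(d)
  expect_lt(abs(f_flat$theta["lambda"] - o["lambda"]), 0.05 + 1e-8)
  expect_lt(abs(f_flat$theta["mu"] - o["mu"]), 0.05 + 1e-8)
  expect_gte(f_flat$log_lik, o["loglik"] - 1e-6)
})

test_that("a zero-width prior pins the MAP at the prior mean", {
  d <- simulate_choices(build_schedule(27), 1.5, 1, -1, seed = 28)
  prior <- group_prior(c(lambda = 2, mu = 0.8, c = -0.3),
                       c(lambda = 1e-8, mu = 1e-8, c = 1e-8))
  f <- fit_map_individual(d, prior, "full", seed = 29)
  expect_equal(unname(f$theta), c(2, 0.8, -0.3), tolerance = 1e-3)
})

test_that("the no-bias variant fixes c at zero and fits two parameters", {
  d <- simulate_choices(build_schedule(30), 1.5, 1, 0, seed = 31)
  f <- fit_map_individual(d, flat_prior("no_bias"), "no_bias", seed = 32)
  expect_named(f$theta, c("lambda", "mu"))
  # reduced-model likelihood cannot beat the full model at its MAP
  ffull <- fit_map_individual(d, flat_prior("full"), "full", seed = 32)
  expect_lte(f$log_lik, ffull$log_lik + 1e-8)
})

test_that("group moment update matches two-point algebra and a naive loop", {
  h <- diag(c(1e8, 1e8, 1e8))  # posterior variances ~ 0
  f1 <- stub_fit(c(lambda = 0, mu = 0, c = 0), h)
  f2 <- stub_fit(c(lambda = 2, mu = 2, c = 2), h, id = "S2")
  pr <- update_group_moments(list(f1, f2))
  expect_equal(unname(pr$mean), c(1, 1, 1))
  expect_equal(unname(pr$var), c(1, 1, 1), tolerance = 1e-6)

  # degenerate population collapses to the variance floor
  pr2 <- update_group_moments(list(f1, f1))
  expect_equal(unname(pr2$var), rep(1e-3, 3))

  # random fits vs naive loop
  set.seed(33)
  fits <- lapply(1:6, function(i) {
    a <- matrix(rnorm(9), 3)
    stub_fit(c(lambda = runif(1, 0, 3), mu = runif(1, 0, 2),
               c = rnorm(1)), crossprod(a) + diag(3), id = paste0("S", i))
  })
  naive <- naive_group_moments(fits)
  got <- update_group_moments(fits)
  expect_equal(unname(got$mean), unname(naive$mean), tolerance = 1e-12)
  expect_equal(unname(got$var), unname(naive$var), tolerance = 1e-12)
})

test_that("hierarchical fit recovers group structure and converges", {
  pool <- simulate_pool(15, seed = 34)
  hf <- fit_hierarchical(pool$data, "full", tol = 1e-3, max_iter = 100,
                         seed = 35)
  expect_true(hf$converged)
  expect_equal(hf$n_units, 15)
  expect_lt(abs(hf$prior$mean["lambda"] - 1.3), 0.5)
  expect_lt(abs(hf$prior$mean["mu"] - 1.0), 0.35)
  # per-subject recovery beats chance comfortably
  expect_gt(cor(pool$truth[, "lambda"], fit_parameters(hf)$lambda), 0.7)
  # EM objective is non-decreasing along the trace
  obj <- unique(hf$trace[, c("iteration", "objective")])$objective
  expect_true(all(diff(obj) > -1e-6))
  # convergence trace shrinks toward zero
  expect_lt(dplyr::last(hf$trace$delta), 1e-3)
})

test_that("tol = Inf stops after one iteration; a single unit terminates", {
  pool <- simulate_pool(4, seed = 36)
  hf <- fit_hierarchical(pool$data, "full", tol = Inf, max_iter = 100,
                         seed = 37)
  expect_equal(max(hf$trace$iteration), 1)
  one <- pool$data[pool$data$subject_id == "S001", ]
  hf1 <- fit_hierarchical(one, "full", tol = 1e-3, max_iter = 100, seed = 38)
  expect_equal(hf1$n_units, 1)
  ml <- fit_map_individual(one, flat_prior("full"), "full", seed = 39)
  expect_lt(max(abs(hf1$prior$mean - ml$theta)), 0.35)
})

test_that("strategy flags pool the right units", {
  co <- generate_cohort(cohort_config(n_hc = 2, n_ndpd = 2, n_dpd = 2,
                                      seed = 40))
  pat <- fit_hierarchical(co$choices, "full", strategy = "patients_only",
                          tol = Inf, max_iter = 1, seed = 41)
  expect_equal(pat$n_units, 8)  # 4 patients x 2 sessions
  expect_false(any(vapply(pat$fits, `[[`, "", "group") == "HC"))

  per <- fit_hierarchical(co$choices, "full",
                          strategy = "controls_plus_patients_per_session",
                          tol = Inf, max_iter = 1, seed = 42)
  expect_named(per, c("OFF", "ON"))
  expect_equal(per$OFF$n_units, 6)  # 2 HC + 4 patients OFF
  expect_equal(per$ON$n_units, 6)
})

test_that("boundary screening lists only fits at the box edge", {
  h <- diag(3)
  interior <- stub_fit(c(lambda = 1.2, mu = 0.9, c = -1), h)
  expect_equal(nrow(screen_boundary(list(interior))), 0)
  edge <- stub_fit(c(lambda = 10, mu = 0.9, c = -1), h, id = "S9",
                   at_boundary = TRUE)
  rep <- screen_boundary(list(interior, edge))
  expect_equal(rep$subject_id, "S9")
  expect_equal(rep$parameter, "lambda")
  expect_equal(rep$bound, 10)
})

test_that("a saturating generator is flagged at the boundary", {
  # true c beyond the box (clipped to +10) drives near-universal acceptance
  d <- simulate_choices(build_schedule(43), 1, 0.1, 10, seed = 44)
  f <- fit_map_individual(d, flat_prior("full"), "full", seed = 45)
  expect_true(f$at_boundary)
  expect_gt(nrow(screen_boundary(list(f))), 0)
})
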