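test_that("default cohort reproduces the study design counts", {
  co <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(co$clinical), 66)
  expect_equal(table(co$clinical$group)[["HC"]], 23)
  expect_equal(table(co$clinical$group)[["PD_nondep"]], 22)
  expect_equal(table(co$clinical$group)[["PD_dep_hist"]], 21)
  expect_equal(nrow(co$choices), 18421)  # (22 + 21) * 2 * 169 + 23 * 169
  # HC tested once, patients twice
  sessions <- table(unique(co$choices[, c("subject_id", "session")])$session)
  expect_equal(sessions[["single"]], 23)
  expect_equal(sessions[["ON"]], 43)
  expect_equal(sessions[["OFF"]], 43)
  # every subject-session is a complete 169-trial schedule over the grid
  one <- co$choices[co$choices$subject_id == "S001", ]
  expect_equal(nrow(unique(one[, c("gain", "loss")])), 169)
})

test_that("same seed gives an identical cohort, different seed does not", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  c_ <- generate_cohort(cohort_config(seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$choices$accepted, c_$choices$accepted))
})

test_that("true parameters stay inside the model bounds and BDI is a count", {
  co <- generate_cohort(cohort_config(seed = 2))
  expect_true(all(co$truth$lambda >= 0 & co$truth$lambda <= 10))
  expect_true(all(co$truth$mu >= 0 & co$truth$mu <= 10))
  expect_true(all(co$truth$c >= -10 & co$truth$c <= 10))
  expect_true(all(co$clinical$bdi_off >= 0))
  expect_true(all(co$clinical$bdi_off == round(co$clinical$bdi_off)))
  # counterbalanced session order within patient groups
  pat <- co$clinical[co$clinical$group != "HC", ]
  expect_true(all(table(pat$group, pat$first_session) >= 10))
})

test_that("default config builds in the three study signatures", {
  co <- generate_cohort(cohort_config(seed = 3))
  tw <- tidyr::pivot_wider(
    co$truth[co$truth$session %in% c("ON", "OFF"), ],
    names_from = "session", values_from = c("lambda", "mu", "c")
  )
  tw <- dplyr::left_join(tw, co$clinical, by = c("subject_id", "group"))
  # medication raises the gambling bias in nondepressed PD
  nd <- tw[tw$group == "PD_nondep", ]
  expect_gt(mean(nd$c_ON - nd$c_OFF), 0.5)
  # higher OFF-state depression couples with larger drug-induced drops in
  # loss aversion
  expect_lt(cor(tw$bdi_off, tw$lambda_ON - tw$lambda_OFF), 0)
  # the depression-history group carries higher OFF-state BDI
  expect_gt(mean(tw$bdi_off[tw$group == "PD_dep_hist"]),
            mean(tw$bdi_off[tw$group == "PD_nondep"]))
})

test_that("zero BDI coupling leaves the drug effect on lambda uncorrelated", {
  cfg <- cohort_config(n_hc = 1, n_ndpd = 100, n_dpd = 100,
                       lambda_bdi_slope = 0, seed = 4)
  co <- generate_cohort(cfg)
  tw <- tidyr::pivot_wider(
    co$truth[co$truth$session %in% c("ON", "OFF"), ],
    names_from = "session", values_from = c("lambda", "mu", "c")
  )
  tw <- dplyr::left_join(tw, co$clinical, by = c("subject_id", "group"))
  expect_lt(abs(cor(tw$bdi_off, tw$lambda_ON - tw$lambda_OFF)), 0.15)
})

test_that("configured c drug effect shows up at its set size", {
  cfg <- cohort_config(n_hc = 1, n_ndpd = 150, n_dpd = 1,
                       drug_effect_c = c(PD_nondep = 1.5, PD_dep_hist = 0),
                       c_on_sd = 0.3, seed = 8)
  co <- generate_cohort(cfg)
  tw <- tidyr::pivot_wider(
    co$truth[co$truth$group == "PD_nondep", ],
    names_from = "session", values_from = c("lambda", "mu", "c")
  )
  d <- tw$c_ON - tw$c_OFF
  expect_lt(abs(mean(d) - 1.5), 3 * sd(d) / sqrt(length(d)) + 0.05)
})

test_that("contaminants behave as designed", {
  sched <- build_schedule(12)
  inv <- generate_contaminant("inverted", sched, seed = 13)
  by_loss <- tapply(inv$accepted, inv$loss, mean)
  expect_gt(cor(as.numeric(names(by_loss)), as.numeric(by_loss)), 0.8)

  rnd <- generate_contaminant("random", sched, seed = 0)
  ci <- qbinom(c(0.005, 0.995), 169, 0.5)
  expect_gte(sum(rnd$accepted), ci[1])
  expect_lte(sum(rnd$accepted), ci[2])
})

test_that("cohort config round-trips through YAML", {
  cfg <- cohort_config(n_ndpd = 10, lambda_bdi_slope = -0.07, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back$n_ndpd, 10)
  expect_equal(back$lambda_bdi_slope, -0.07)
  expect_equal(back$lambda_mean, cfg$lambda_mean)
  expect_identical(generate_cohort(back)$choices$accepted,
                   generate_cohort(cfg)$choices$accepted)
})
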