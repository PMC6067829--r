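#' Synthetic cohorts emulating a two-session medication-withdrawal design
#'
#' The generator produces study-like cohorts with three groups — healthy
#' controls (`HC`, tested once), nondepressed Parkinson's patients
#' (`PD_nondep`) and patients with a depression history (`PD_dep_hist`),
#' each tested ON and OFF dopaminergic medication — 169 mixed gambles per
#' session, group-typical choice-model parameters, depression (BDI) scores,
#' and two built-in effects: a medication-induced increase of the gambling
#' bias `c` in nondepressed patients, and a negative coupling between
#' OFF-state depression severity and the medication effect on loss aversion
#' \eqn{\lambda}. Ground-truth parameters are returned for recovery tests.
#'
#' @name synthetic_cohort
NULL

#' Default cohort configuration
#'
#' Group centres are placed at the observed per-group medians of the fitted
#' parameters and the published group BDI means; spreads are conservative
#' choices since subject-level variances are not published. The ON-session
#' gambling bias in nondepressed patients is shifted by `drug_effect_c`
#' (+1.66 by default, the OFF-to-ON median shift), and the per-subject
#' medication effect on \eqn{\lambda} is `lambda_bdi_slope *
#' (BDI_OFF - group BDI mean) + noise`, so a negative slope yields a
#' negative correlation between OFF-state BDI and the drug effect on
#' \eqn{\lambda}.
#'
#' @param n_hc,n_ndpd,n_dpd Group sizes (controls, nondepressed PD, PD with
#'   depression history).
#' @param lambda_mean,mu_mean,c_mean Named per-group OFF-session (or
#'   single-session) parameter centres.
#' @param lambda_sd,mu_sd,c_sd Between-subject SDs of the OFF parameters.
#' @param drug_effect_c Named per-patient-group OFF-to-ON shift of `c`.
#' @param c_on_sd,mu_on_sd SDs of the session noise added to `c` and `mu`
#'   ON.
#' @param lambda_bdi_slope Coupling of the \eqn{\lambda} drug effect to
#'   OFF-state BDI (units of \eqn{\lambda} per BDI point; negative couples
#'   higher depression to larger drug-induced drops in loss aversion).
#' @param lambda_on_sd SD of the residual \eqn{\lambda} drug-effect noise.
#' @param bdi_mean,bdi_sd Named per-group BDI centres and SDs (OFF session;
#'   single for controls).
#' @param bdi_drug_effect Named per-patient-group OFF-to-ON BDI shift
#'   (negative = improvement ON).
#' @param bdi_on_sd SD of session noise on BDI ON.
#' @param led_mean,led_sd Named per-patient-group levodopa-equivalent dose
#'   (mg/day).
#' @param n_icd Named per-patient-group count of impulse-control-disorder
#'   flags.
#' @param seed Integer seed (mandatory for generation).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_hc = 23, n_ndpd = 22, n_dpd = 21,
    lambda_mean = c(HC = 1.37, PD_nondep = 1.01, PD_dep_hist = 1.51),
    lambda_sd = 0.6,
    mu_mean = c(HC = 1.06, PD_nondep = 0.89, PD_dep_hist = 0.93),
    mu_sd = 0.4,
    c_mean = c(HC = -0.65, PD_nondep = -2.71, PD_dep_hist = -1.73),
    c_sd = 1.5,
    drug_effect_c = c(PD_nondep = 1.66, PD_dep_hist = 0.43),
    c_on_sd = 0.8,
    mu_on_sd = 0.2,
    lambda_bdi_slope = -0.05,
    lambda_on_sd = 0.25,
    bdi_mean = c(HC = 3.1, PD_nondep = 4.0, PD_dep_hist = 9.9),
    bdi_sd = c(HC = 2.1, PD_nondep = 2.3, PD_dep_hist = 6.1),
    bdi_drug_effect = c(PD_nondep = 0, PD_dep_hist = -1.5),
    bdi_on_sd = 2.0,
    led_mean = c(PD_nondep = 627, PD_dep_hist = 551),
    led_sd = c(PD_nondep = 275, PD_dep_hist = 248),
    n_icd = c(PD_nondep = 1, PD_dep_hist = 4),
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_hc >= 1, cfg$n_ndpd >= 1, cfg$n_dpd >= 1)
  sds <- c(cfg$lambda_sd, cfg$mu_sd, cfg$c_sd, cfg$c_on_sd, cfg$mu_on_sd,
           cfg$lambda_on_sd, unname(cfg$bdi_sd), cfg$bdi_on_sd,
           unname(cfg$led_sd))
  stopifnot(all(sds >= 0))
  structure(cfg, class = "cohort_config")
}

#' Read/write a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path YAML file path.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(cohort_config, raw)
}

rtnorm <- function(n, mean, sd, lower, upper) {
  # inverse-CDF truncated normal; exact and vectorized
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject OFF-session parameters from truncated normals inside
#' the model bounds, constructs ON-session parameters from the configured
#' drug effects plus noise, draws BDI / LED / ICD covariates, builds a
#' fresh randomized schedule per subject-session, and simulates every
#' choice through the prospect-theory model. Session order alternates
#' within each patient group (counterbalancing) and is recorded.
#'
#' @param config A [cohort_config()]; its `seed` drives all randomness.
#' @return List with `choices` (trial-level tibble), `clinical` (one row
#'   per subject: `bdi_off`, `bdi_on`, `led`, `icd_flag`, `first_session`)
#'   and `truth` (true parameters per subject-session).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    groups <- c(rep("HC", cfg$n_hc), rep("PD_nondep", cfg$n_ndpd),
                rep("PD_dep_hist", cfg$n_dpd))
    ids <- sprintf("S%03d", seq_along(groups))
    schedule_seeds <- sample.int(2^30, length(ids) * 2)

    clinical <- vector("list", length(ids))
    truth <- vector("list", length(ids))
    choices <- vector("list", length(ids))
    icd_left <- cfg$n_icd
    order_counter <- c(PD_nondep = 0L, PD_dep_hist = 0L)

    for (i in seq_along(ids)) {
      grp <- groups[i]
      is_patient <- grp != "HC"

      bdi_off <- max(0, round(stats::rnorm(1, cfg$bdi_mean[grp], cfg$bdi_sd[grp])))
      lam_off <- rtnorm(1, cfg$lambda_mean[grp], cfg$lambda_sd, 0, 10)
      mu_off <- rtnorm(1, cfg$mu_mean[grp], cfg$mu_sd, 0, 10)
      c_off <- min(10, max(-10, stats::rnorm(1, cfg$c_mean[grp], cfg$c_sd)))

      if (is_patient) {
        d_lam <- cfg$lambda_bdi_slope * (bdi_off - cfg$bdi_mean[grp]) +
          stats::rnorm(1, 0, cfg$lambda_on_sd)
        lam_on <- min(10, max(0, lam_off + d_lam))
        mu_on <- min(10, max(0, mu_off + stats::rnorm(1, 0, cfg$mu_on_sd)))
        c_on <- min(10, max(-10, c_off + cfg$drug_effect_c[grp] +
                              stats::rnorm(1, 0, cfg$c_on_sd)))
        bdi_on <- max(0, round(bdi_off + cfg$bdi_drug_effect[grp] +
                                 stats::rnorm(1, 0, cfg$bdi_on_sd)))
        led <- max(0, stats::rnorm(1, cfg$led_mean[grp], cfg$led_sd[grp]))
        icd <- icd_left[grp] > 0
        if (icd) icd_left[grp] <- icd_left[grp] - 1L
        order_counter[grp] <- order_counter[grp] + 1L
        first_session <- if (order_counter[grp] %% 2L == 1L) "ON" else "OFF"
        sessions <- c("OFF", "ON")
        pars <- list(OFF = c(lambda = lam_off, mu = mu_off, c = c_off),
                     ON = c(lambda = lam_on, mu = mu_on, c = c_on))
      } else {
        bdi_on <- NA_real_
        led <- NA_real_
        icd <- FALSE
        first_session <- "single"
        sessions <- "single"
        pars <- list(single = c(lambda = lam_off, mu = mu_off, c = c_off))
      }

      clinical[[i]] <- tibble::tibble(
        subject_id = ids[i], group = grp,
        bdi_off = bdi_off, bdi_on = bdi_on, led = led, icd_flag = icd,
        first_session = first_session
      )
      truth[[i]] <- dplyr::bind_rows(lapply(sessions, function(ses) {
        tibble::tibble(subject_id = ids[i], group = grp, session = ses,
                       lambda = pars[[ses]]["lambda"], mu = pars[[ses]]["mu"],
                       c = pars[[ses]]["c"])
      }))
      choices[[i]] <- dplyr::bind_rows(lapply(seq_along(sessions), function(k) {
        ses <- sessions[k]
        sched <- build_schedule(schedule_seeds[2 * (i - 1) + k])
        simulate_choices(sched, pars[[ses]]["lambda"], pars[[ses]]["mu"],
                         pars[[ses]]["c"],
                         seed = schedule_seeds[2 * (i - 1) + k] + 1,
                         subject_id = ids[i], group = grp, session = ses)
      }))
    }

    list(
      choices = dplyr::bind_rows(choices),
      clinical = dplyr::bind_rows(clinical),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Generate a contaminant subject
#'
#' Two failure modes seen in real task data: `"inverted"` subjects accept
#' more as losses grow and gains shrink (a sign-flipped utility maximizer,
#' simulated with a negative effective inverse temperature), and
#' `"random"` subjects choose with probability 0.5 on every trial.
#'
#' @param kind `"inverted"` or `"random"`.
#' @param schedule Schedule from [build_schedule()].
#' @param seed Integer seed.
#' @param strength Magnitude of the negative effective `mu` for the
#'   inverted kind.
#' @param subject_id,group,session Identifiers stamped on the rows.
#' @return A choice tibble.
#' @export
generate_contaminant <- function(kind = c("inverted", "random"), schedule,
                                 seed, strength = 10,
                                 subject_id = "contam", group = "PD_nondep",
                                 session = "OFF") {
  kind <- match.arg(kind)
  sug <- subjective_utility(schedule$gain, schedule$loss, lambda = 1)
  p <- switch(kind,
    inverted = stats::plogis(-strength * sug),
    random = rep(0.5, nrow(schedule))
  )
  acc <- with_local_seed(seed, stats::runif(length(p)) < p)
  tibble::tibble(
    subject_id = subject_id, group = group, session = session,
    trial_index = seq_along(p), gain = schedule$gain, loss = schedule$loss,
    accepted = as.logical(acc)
  )
}
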