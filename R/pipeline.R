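#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the cohort generator
#' settings, the master seed (which overrides the cohort seed so one seed
#' fixes the whole run), fitting tolerances, the model variants to fit,
#' and statistics settings.
#'
#' @param cohort A [cohort_config()].
#' @param seed Master seed for the run (mandatory).
#' @param tol,max_iter Hierarchical-fit convergence settings.
#' @param variants Model variants to fit (`"full"`, `"no_bias"`).
#' @param n_starts Optimization starts per unit.
#' @param n_boot Bootstrap resamples for median standard errors.
#' @param alpha Significance level used by screening and routing.
#' @param fit_controls Also run the controls-plus-patients per-session
#'   fits (needed for control-group parameter estimates); disable to
#'   shorten exploratory runs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), seed = 1L,
                            tol = 1e-4, max_iter = 500,
                            variants = c("full", "no_bias"),
                            n_starts = 5, n_boot = 1e5, alpha = 0.05,
                            fit_controls = TRUE) {
  stopifnot(tol > 0, max_iter >= 1, length(seed) == 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation, behavioural screening (subjects
#' with any excluded session are dropped before fitting), hierarchical
#' fitting of each model variant to patients only (both groups and both
#' sessions pooled under one prior) and — when `fit_controls` is `TRUE` —
#' to controls plus patients separately per drug session, Bayesian model
#' comparison by NLME, model-free metrics (acceptance proportions and
#' loss-sensitivity curves), and the statistical battery (drug effects on
#' parameters, parameter--BDI correlations with a Fisher r-to-z group
#' comparison, mixed ANOVAs on BDI and acceptance rate). All stages are
#' deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all artifacts (CSV/JSON
#'   tables and a manifest) are written there.
#' @return A list with elements `cohort`, `screen`, `excluded_subjects`,
#'   `fits` (per variant), `comparison`, `fits_with_controls`,
#'   `parameters`, `parameter_table`, `metrics`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  cfg$cohort$seed <- cfg$seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", generate_cohort(cfg$cohort))

  screen <- stage("screen", screen_dataset(cohort$choices, alpha = cfg$alpha))
  excluded <- sort(unique(screen$subject_id[screen$verdict != "include"]))
  kept <- cohort$choices[!cohort$choices$subject_id %in% excluded, ]

  fits <- stage("fit", {
    out <- lapply(cfg$variants, function(v) {
      fit_hierarchical(kept, variant = v, strategy = "patients_only",
                       tol = cfg$tol, max_iter = cfg$max_iter,
                       n_starts = cfg$n_starts, seed = cfg$seed)
    })
    names(out) <- cfg$variants
    out
  })

  comparison <- stage("compare", {
    ev <- lapply(fits, compute_nlme)
    res <- list(
      evidence = lapply(ev, function(e) list(nlme = e$nlme, m = e$m,
                                             n_units = e$n_units))
    )
    if (all(c("full", "no_bias") %in% names(ev))) {
      res$winner <- select_model(ev$full, ev$no_bias)
    }
    res
  })

  fits_controls <- NULL
  if (isTRUE(cfg$fit_controls) && any(cohort$choices$group == "HC")) {
    fits_controls <- stage("fit_controls", {
      fit_hierarchical(kept, variant = cfg$variants[1],
                       strategy = "controls_plus_patients_per_session",
                       tol = cfg$tol, max_iter = cfg$max_iter,
                       n_starts = cfg$n_starts, seed = cfg$seed)
    })
  }

  main_variant <- cfg$variants[1]
  params <- fit_parameters(fits[[main_variant]])
  if (!is.null(fits_controls)) {
    hc <- fit_parameters(fits_controls$OFF)
    params <- dplyr::bind_rows(params, hc[hc$group == "HC", ])
  }

  parameter_table <- stage("report", {
    render_parameter_table(params, n_boot = cfg$n_boot, seed = cfg$seed)
  })

  metrics <- stage("metrics", {
    curves <- lapply(split_units_by(kept, c("group", "session")),
                     loss_sensitivity_curve)
    list(
      proportion_accepted = proportion_accepted(kept, c("group", "session")),
      proportion_by_subject = proportion_accepted(kept,
                                                  c("subject_id", "group", "session")),
      loss_sensitivity = tibble::tibble(
        stratum = names(curves),
        slope = vapply(curves, `[[`, 0, "slope")
      ),
      curves = curves
    )
  })

  stats <- stage("stats", run_stat_battery(params, cohort$clinical,
                                           metrics$proportion_by_subject,
                                           excluded))

  manifest <- list(
    seed = cfg$seed,
    tol = cfg$tol,
    max_iter = cfg$max_iter,
    variants = cfg$variants,
    n_boot = cfg$n_boot,
    alpha = cfg$alpha,
    cohort_seed = cfg$cohort$seed,
    n_subjects = nrow(cohort$clinical),
    excluded_subjects = excluded,
    n_units_fitted = fits[[main_variant]]$n_units,
    fit_converged = vapply(fits, `[[`, TRUE, "converged"),
    winner = comparison$winner %||% NA_character_,
    package_version = as.character(utils::packageVersion("gambleb"))
  )

  result <- list(cohort = cohort, screen = screen,
                 excluded_subjects = excluded, fits = fits,
                 comparison = comparison, fits_with_controls = fits_controls,
                 parameters = params, parameter_table = parameter_table,
                 metrics = metrics, stats = stats, manifest = manifest)

  if (!is.null(out_dir)) write_run_artifacts(result, cfg, out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_units_by <- function(data, keys) {
  key <- interaction(lapply(keys, function(k) data[[k]]), drop = TRUE,
                     sep = ":")
  split(data, key)
}

# Statistical battery over the fitted parameters and clinical covariates,
# mirroring the analysis order of the study: drug effects within the
# nondepressed group, parameter-BDI correlations across patients with a
# per-group breakdown and Fisher r-to-z contrast, and mixed ANOVAs for the
# normally distributed outcomes (BDI, acceptance rate).
run_stat_battery <- function(params, clinical, prop_by_subject, excluded) {
  clinical <- clinical[!clinical$subject_id %in% excluded, ]
  patients <- params[params$group %in% c("PD_nondep", "PD_dep_hist") &
                       params$session %in% c("ON", "OFF"), ]
  rows <- list()

  for (par in c("c", "lambda", "mu")) {
    nd <- patients[patients$group == "PD_nondep", ]
    wide <- tidyr::pivot_wider(nd[, c("subject_id", "session", par)],
                               names_from = "session",
                               values_from = dplyr::all_of(par))
    if (nrow(wide) >= 3 && !anyNA(wide$ON) && !anyNA(wide$OFF) &&
        any(wide$ON != wide$OFF)) {
      r <- wilcoxon_signed_rank(wide$ON, wide$OFF)
      r$test <- paste0(par, ": ON vs OFF, PD_nondep, wilcoxon")
      rows[[length(rows) + 1]] <- r
    }
  }

  det <- drug_effect_table(patients, clinical)
  if (nrow(det) >= 4) {
    r1 <- correlation(det$bdi_off, det$d_lambda, "spearman")
    r1$test <- "d_lambda vs BDI_OFF, patients, spearman"
    r2 <- correlation(det$d_bdi, det$d_lambda, "spearman")
    r2$test <- "d_lambda vs d_BDI, patients, spearman"
    rows <- c(rows, list(r1, r2))

    per_group <- lapply(split(det, det$group), function(g) {
      if (nrow(g) >= 4) correlation(g$d_bdi, g$d_lambda, "spearman") else NULL
    })
    per_group <- per_group[!vapply(per_group, is.null, TRUE)]
    for (gname in names(per_group)) {
      rg <- per_group[[gname]]
      rg$test <- paste0("d_lambda vs d_BDI, ", gname, ", spearman")
      rows[[length(rows) + 1]] <- rg
    }
    if (all(c("PD_dep_hist", "PD_nondep") %in% names(per_group)) &&
        all(abs(c(per_group$PD_dep_hist$statistic,
                  per_group$PD_nondep$statistic)) < 1)) {
      fz <- fisher_rz_compare(
        per_group$PD_dep_hist$statistic, per_group$PD_dep_hist$n,
        per_group$PD_nondep$statistic, per_group$PD_nondep$n
      )
      fz$test <- "d_lambda vs d_BDI: PD_dep_hist vs PD_nondep, fisher_rz"
      rows[[length(rows) + 1]] <- fz
    }
  }

  pat_clin <- clinical[clinical$group != "HC", ]
  if (nrow(pat_clin) >= 4) {
    bdi_long <- tidyr::pivot_longer(
      pat_clin[, c("subject_id", "group", "bdi_off", "bdi_on")],
      cols = c("bdi_off", "bdi_on"), names_to = "session",
      values_to = "value"
    )
    bdi_long$session <- toupper(sub("bdi_", "", bdi_long$session))
    av <- mixed_anova(bdi_long)
    av$test <- paste0("BDI: ", sub("mixed_anova_", "", av$test), ", mixed_anova")
    rows[[length(rows) + 1]] <- av
  }

  prop_pat <- prop_by_subject[prop_by_subject$group != "HC" &
                                prop_by_subject$session %in% c("ON", "OFF"), ]
  if (nrow(prop_pat) >= 8) {
    pa <- prop_pat[, c("subject_id", "group", "session", "prop_accepted")]
    names(pa)[4] <- "value"
    av2 <- mixed_anova(pa)
    av2$test <- paste0("prop_accepted: ", sub("mixed_anova_", "", av2$test),
                       ", mixed_anova")
    rows[[length(rows) + 1]] <- av2
  }

  dplyr::bind_rows(rows)
}

#' Median (range) parameter table per group and session
#'
#' Summarizes fitted parameters the way group results are typically
#' tabulated for this task: the median, the range (max minus min) and a
#' bootstrap standard error of the median, per parameter, group and
#' session.
#'
#' @param params Tidy parameter tibble (see [fit_parameters()]).
#' @param n_boot Bootstrap resamples for the median SE.
#' @param seed Integer seed for the bootstrap.
#' @return Tibble with `group`, `session`, `parameter`, `n`, `median`,
#'   `range`, `se_median`.
#' @export
render_parameter_table <- function(params, n_boot = 1e5, seed = 1) {
  long <- tidyr::pivot_longer(
    params[, c("subject_id", "group", "session", "lambda", "mu", "c")],
    cols = c("lambda", "mu", "c"), names_to = "parameter",
    values_to = "value"
  )
  strata <- split_units_by(long, c("group", "session", "parameter"))
  if (any(vapply(strata, nrow, 1L) == 0)) stop("empty stratum")
  out <- lapply(seq_along(strata), function(i) {
    s <- strata[[i]]
    se <- if (nrow(s) >= 2) {
      bootstrap_median_se(s$value, n_boot = n_boot, seed = seed + i)
    } else 0
    tibble::tibble(
      group = s$group[1], session = s$session[1], parameter = s$parameter[1],
      n = nrow(s), median = stats::median(s$value),
      range = max(s$value) - min(s$value), se_median = se
    )
  })
  out <- dplyr::bind_rows(out)
  out[order(out$parameter, out$group, out$session), ]
}

# Serialize all run artifacts. The manifest deliberately contains no
# timestamps or absolute paths so identical config + seed gives
# byte-identical output.
write_run_artifacts <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) utils::write.csv(x, file.path(out_dir, name),
                                          row.names = FALSE)
  write_choices_csv(result$cohort$choices, file.path(out_dir, "choices.csv"))
  w(result$cohort$clinical, "clinical.csv")
  w(result$cohort$truth, "true_parameters.csv")
  w(result$screen, "screen.csv")
  w(result$parameters, "fitted_parameters.csv")
  w(result$parameter_table, "parameter_table.csv")
  w(result$metrics$proportion_accepted, "proportion_accepted.csv")
  w(result$metrics$loss_sensitivity, "loss_sensitivity_slopes.csv")
  w(result$stats, "stats.csv")
  for (v in names(result$fits)) {
    f <- result$fits[[v]]
    jsonlite::write_json(list(
      variant = v,
      prior = list(mean = as.list(f$prior$mean), var = as.list(f$prior$var)),
      converged = f$converged,
      n_units = f$n_units,
      units = lapply(f$fits, function(u) list(
        subject_id = u$subject_id, session = u$session,
        theta = as.list(u$theta), log_lik = u$log_lik,
        log_det_hessian = log(det(u$hessian)), at_boundary = u$at_boundary
      )),
      trace = result$fits[[v]]$trace
    ), file.path(out_dir, paste0("fit_", v, ".json")),
    auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$comparison,
                       file.path(out_dir, "model_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
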