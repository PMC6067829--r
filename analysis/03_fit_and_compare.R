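#!/usr/bin/env Rscript
# Hierarchical empirical-Bayes fitting and Bayesian model comparison.
# Two passes, as in the study design: (a) patients only, both groups and
# both drug sessions pooled under one prior, fitted with the full model
# (lambda, mu, c) and the reduced model (c forced to 0) and compared by
# negative log-model evidence; (b) controls plus patients per drug
# session, to place the control group on the same footing.

library(gambleb)
library(jsonlite)

seed <- if (length(commandArgs(TRUE)) >= 1) {
  as.integer(commandArgs(TRUE)[1])
} else 20260920L

choices <- read_choices_csv("results/cohort/choices.csv")
screen <- read.csv("results/screen.csv")
excluded <- unique(screen$subject_id[screen$verdict != "include"])
kept <- choices[!choices$subject_id %in% excluded, ]
cat("Fitting", length(unique(kept$subject_id)), "subjects (",
    length(excluded), "excluded )\n")

dir.create("results/fits", recursive = TRUE, showWarnings = FALSE)

evidence <- list()
params <- NULL
for (variant in c("full", "no_bias")) {
  t0 <- Sys.time()
  fit <- fit_hierarchical(kept, variant = variant,
                          strategy = "patients_only",
                          tol = 1e-4, max_iter = 500, seed = seed)
  ev <- compute_nlme(fit)
  evidence[[variant]] <- ev
  cat(sprintf("  %-8s NLME %.1f over %d units (%d free params; %.1f s; converged: %s)\n",
              variant, ev$nlme, ev$n_units, ev$m,
              as.numeric(Sys.time() - t0, units = "secs"), fit$converged))
  write_json(list(
    variant = variant,
    prior = list(mean = as.list(fit$prior$mean), var = as.list(fit$prior$var)),
    converged = fit$converged,
    nlme = ev$nlme,
    units = lapply(fit$fits, function(u) list(
      subject_id = u$subject_id, session = u$session, theta = as.list(u$theta),
      log_lik = u$log_lik, log_det_hessian = log(det(u$hessian)),
      at_boundary = u$at_boundary
    ))
  ), sprintf("results/fits/patients_%s.json", variant),
  auto_unbox = TRUE, digits = NA)
  if (variant == "full") params <- fit_parameters(fit)
}

winner <- select_model(evidence$full, evidence$no_bias)
cat("Winning model:", winner, "( NLME margin",
    round(evidence$no_bias$nlme - evidence$full$nlme, 1), ")\n")
write_json(list(
  nlme_full = evidence$full$nlme,
  nlme_no_bias = evidence$no_bias$nlme,
  winner = winner
), "results/fits/model_comparison.json", auto_unbox = TRUE, digits = NA)

# pass (b): controls + patients per session, winning variant
ctrl <- fit_hierarchical(kept, variant = winner,
                         strategy = "controls_plus_patients_per_session",
                         tol = 1e-4, max_iter = 500, seed = seed)
hc <- fit_parameters(ctrl$OFF)
params <- rbind(params, hc[hc$group == "HC", ])
write.csv(params, "results/fits/fitted_parameters.csv", row.names = FALSE)

boundary <- screen_boundary(ctrl$OFF)
cat("Units at parameter bounds (controls pass, OFF):", nrow(boundary), "\n")

tab <- render_parameter_table(params, n_boot = 1e5, seed = seed)
write.csv(tab, "results/fits/parameter_table.csv", row.names = FALSE)
cat("Median (range) parameter table written; c medians by group/session:\n")
print(as.data.frame(tab[tab$parameter == "c",
                        c("group", "session", "median", "range", "se_median")]))
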