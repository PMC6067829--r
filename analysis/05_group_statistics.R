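#!/usr/bin/env Rscript
# The statistical battery over fitted parameters, acceptance rates and
# clinical scores: normality-routed within-subject (Wilcoxon) and
# between-group (Mann-Whitney) contrasts, mixed ANOVAs for BDI and
# acceptance rate, the drug-effect correlations with depression severity,
# and the Fisher r-to-z contrast between patient groups.

library(gambleb)

seed <- if (length(commandArgs(TRUE)) >= 1) {
  as.integer(commandArgs(TRUE)[1])
} else 20260920L

params <- read.csv("results/fits/fitted_parameters.csv")
clinical <- read.csv("results/cohort/clinical.csv")
screen <- read.csv("results/screen.csv")
excluded <- unique(screen$subject_id[screen$verdict != "include"])
clinical <- clinical[!clinical$subject_id %in% excluded, ]

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

# normality routing for the fitted parameters (pooled across patients)
for (par in c("lambda", "mu", "c")) {
  branch <- route_by_normality(params[[par]][params$group != "HC"])
  cat(sprintf("  %-7s -> %s branch\n", par, branch))
}

# within-subject drug effects in nondepressed PD
nd <- params[params$group == "PD_nondep", ]
for (par in c("c", "lambda", "mu")) {
  w <- reshape(nd[, c("subject_id", "session", par)], idvar = "subject_id",
               timevar = "session", direction = "wide")
  res <- wilcoxon_signed_rank(w[[paste0(par, ".ON")]],
                              w[[paste0(par, ".OFF")]])
  cat(sprintf("  %s ON vs OFF (ndPD): V = %g, p = %.4g\n", par,
              res$statistic, res$p))
}

# drug-effect correlations across patients
det <- drug_effect_table(params[params$group != "HC", ], clinical)
r_bdi <- correlation(det$bdi_off, det$d_lambda, "spearman")
r_dbdi <- correlation(det$d_bdi, det$d_lambda, "spearman")
cat(sprintf("  rho(BDI_OFF, d_lambda) = %.3f, p = %.3f (n = %d)\n",
            r_bdi$statistic, r_bdi$p, r_bdi$n))
cat(sprintf("  rho(d_BDI, d_lambda)   = %.3f, p = %.3f (n = %d)\n",
            r_dbdi$statistic, r_dbdi$p, r_dbdi$n))

per_group <- lapply(split(det, det$group), function(g) {
  correlation(g$d_bdi, g$d_lambda, "spearman")
})
fz <- fisher_rz_compare(per_group$PD_dep_hist$statistic,
                        per_group$PD_dep_hist$n,
                        per_group$PD_nondep$statistic,
                        per_group$PD_nondep$n)
cat(sprintf("  group contrast of those correlations: z = %.2f, p = %.3f\n",
            fz$statistic, fz$p))

# mixed ANOVA on BDI (drug within, group between)
bdi <- clinical[clinical$group != "HC",
                c("subject_id", "group", "bdi_off", "bdi_on")]
bdi_long <- reshape(bdi, varying = c("bdi_off", "bdi_on"), v.names = "value",
                    timevar = "session", times = c("OFF", "ON"),
                    direction = "long")
av <- mixed_anova(bdi_long)
cat("  BDI mixed ANOVA:\n")
print(as.data.frame(av[, c("test", "statistic", "df1", "df2", "p")]),
      row.names = FALSE)

# medians with bootstrap SEs for the nonnormal parameters
meds <- render_parameter_table(params, n_boot = 1e5, seed = seed)
out <- dplyr::bind_rows(
  cbind(analysis = "wilcoxon_c_ndPD",
        as.data.frame(wilcoxon_signed_rank(
          nd$c[nd$session == "ON"], nd$c[nd$session == "OFF"]))),
  cbind(analysis = "spearman_bdi_off_dlambda", as.data.frame(r_bdi)),
  cbind(analysis = "spearman_dbdi_dlambda", as.data.frame(r_dbdi)),
  cbind(analysis = "fisher_rz_groups", as.data.frame(fz))
)
write.csv(out, "results/stats/key_statistics.csv", row.names = FALSE)
write.csv(meds, "results/stats/parameter_medians.csv", row.names = FALSE)
write.csv(det, "results/stats/drug_effect_table.csv", row.names = FALSE)
cat("Stats written under results/stats/\n")
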