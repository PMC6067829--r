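#!/usr/bin/env Rscript
# Simulate the study-like cohort: 23 healthy controls tested once, 22
# nondepressed PD patients and 21 PD patients with a depression (history)
# each tested ON and OFF medication, 169 mixed gambles per session.
# Writes trial-level choices, clinical covariates and the ground-truth
# parameters under results/cohort/.

library(gambleb)

seed <- if (length(commandArgs(TRUE)) >= 1) {
  as.integer(commandArgs(TRUE)[1])
} else 20260920L

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
write_cohort_config(cfg, file.path(out, "cohort_config.yaml"))

cohort <- generate_cohort(cfg)
write_choices_csv(cohort$choices, file.path(out, "choices.csv"))
write.csv(cohort$clinical, file.path(out, "clinical.csv"), row.names = FALSE)
write.csv(cohort$truth, file.path(out, "true_parameters.csv"),
          row.names = FALSE)
write_schedule_csv(build_schedule(seed), file.path(out, "example_schedule.csv"))

cat("Simulated cohort with seed", seed, "\n")
cat("  subjects:", nrow(cohort$clinical), "(",
    paste(names(table(cohort$clinical$group)),
          table(cohort$clinical$group), collapse = ", "), ")\n")
cat("  trial rows:", nrow(cohort$choices), "\n")
nd <- subset(cohort$truth, group == "PD_nondep")
cat("  true mean gambling bias c, nondepressed PD: OFF",
    round(mean(nd$c[nd$session == "OFF"]), 2), "-> ON",
    round(mean(nd$c[nd$session == "ON"]), 2), "\n")
cat("Outputs in", out, "\n")
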