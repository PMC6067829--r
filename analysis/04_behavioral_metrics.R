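#!/usr/bin/env Rscript
# Model-free behavioural measures: proportion of accepted gambles per
# group and session, and loss-sensitivity curves (log rejected/accepted
# ratio against relative loss, gains pooled) whose slope tracks loss
# aversion without any model fitting.

library(gambleb)

choices <- read_choices_csv("results/cohort/choices.csv")
screen <- read.csv("results/screen.csv")
excluded <- unique(screen$subject_id[screen$verdict != "include"])
kept <- choices[!choices$subject_id %in% excluded, ]

dir.create("results/metrics", recursive = TRUE, showWarnings = FALSE)

prop <- proportion_accepted(kept, by = c("group", "session"))
write.csv(prop, "results/metrics/proportion_accepted.csv", row.names = FALSE)
cat("Proportion of accepted gambles:\n")
print(as.data.frame(prop))

strata <- split(kept, interaction(kept$group, kept$session, drop = TRUE))
curves <- lapply(strata, loss_sensitivity_curve)
slopes <- data.frame(
  stratum = names(curves),
  slope = vapply(curves, `[[`, 0, "slope")
)
write.csv(slopes, "results/metrics/loss_sensitivity_slopes.csv",
          row.names = FALSE)
curve_points <- do.call(rbind, lapply(names(curves), function(nm) {
  cbind(stratum = nm, as.data.frame(curves[[nm]]$curve))
}))
write.csv(curve_points, "results/metrics/loss_sensitivity_curves.csv",
          row.names = FALSE)
cat("\nLoss-sensitivity slopes (steeper = more loss sensitive):\n")
print(slopes, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- plot_loss_sensitivity(curves)
  ggplot2::ggsave("results/metrics/loss_sensitivity.png", p,
                  width = 7, height = 5, dpi = 150)
  cat("Curve plot written to results/metrics/loss_sensitivity.png\n")
}
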