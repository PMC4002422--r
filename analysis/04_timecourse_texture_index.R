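#!/usr/bin/env Rscript
# The early-degeneration time course: six acquisitions at 10-minute
# intervals, feature selection (first vs last timepoint), class-conditional
# pairwise distances, Sammon projection and the Texture Index with 95%
# confidence intervals and Welch t-tests against the first timepoint.
# Writes results/timecourse/ and a TI figure when a graphics device exists.

suppressPackageStartupMessages(library(speckletex))
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config("timecourse_cells", n_per_group = 10, n_subsets = 3,
                         shape = c(64, 48, 48), seed = 401)
res <- run_experiment(cfg, "results/timecourse")

print(res$ti, digits = 3)
cat("TI non-decreasing:", !is.unsorted(res$ti$ti), "\n")
cat(sprintf("final timepoint vs control: Welch p = %.2e\n",
            res$ti$p_value[nrow(res$ti)]))

stars <- function(p) ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                     ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
if (capabilities("png")) {
  try({
    png("results/timecourse/ti_series.png", width = 800, height = 500)
    ti <- res$ti
    plot(ti$timepoint, ti$ti, type = "b", pch = 19,
         xlab = "time after insult (min)", ylab = "Texture Index",
         main = "Texture Index along the maximum-variance projection",
         ylim = range(c(ti$ti - ti$ci_halfwidth, ti$ti + ti$ci_halfwidth)))
    arrows(ti$timepoint, ti$ti - ti$ci_halfwidth,
           ti$timepoint, ti$ti + ti$ci_halfwidth,
           angle = 90, code = 3, length = 0.04)
    text(ti$timepoint, ti$ti + ti$ci_halfwidth, stars(ti$p_value), pos = 3)
    dev.off()
  }, silent = TRUE)
}
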