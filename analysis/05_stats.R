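#!/usr/bin/env Rscript
# Validation statistics over the pipeline's trait records: per-field
# simple regressions of estimated heights against tape measurements
# (quadrant and plot level) and against dry biomass, replicate-based
# lack-of-fit tests, and the between-field equality-of-lines ANOVA for
# the height-biomass relationship.

library(swardscan)

pipe_dir <- "results/pipeline"
if (!file.exists(file.path(pipe_dir, "traits.csv")))
  stop("run analysis/04_traits.R first (missing ", pipe_dir, "/traits.csv)")

traits <- read.csv(file.path(pipe_dir, "traits.csv"))
pairs_quad <- read.csv(file.path(pipe_dir, "pairs_quadrant.csv"))
stats <- pipeline_statistics(traits, pairs_quad)

report <- swardscan:::stats_report(stats)
writeLines(report, file.path(pipe_dir, "stats_report.txt"))
cat(report, sep = "\n")

r2 <- sapply(c("ryegrass", "timothy"),
             function(f) stats[[f]]$biomass_height$r_squared)
cat(sprintf(
  "\nHeight predicts biomass on the timothy-like field (R2 = %.2f) but not\non the ryegrass-like field (R2 = %.2f): the tillering vs height-growth\ncontrast between the two sward types.\n",
  r2[["timothy"]], r2[["ryegrass"]]))
cat("outputs in", pipe_dir, "\n")
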