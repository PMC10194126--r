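#!/usr/bin/env Rscript
# Nonparametric statistics over the preflex metrics: Shapiro-Wilk normality
# screen, Friedman tests across perturbations within each activity level and
# speed condition, pairwise sign-test post hocs with Bonferroni correction
# and paired Cohen's d, and paired sign tests of dynamic vs quasistatic
# conditions.
#
# Usage: Rscript analysis/05_statistics.R [results_dir]

library(preflexr)

out <- commandArgs(trailingOnly = TRUE)
out <- if (length(out)) out[1] else "results"

metrics <- read.csv(file.path(out, "metrics.csv"))
metrics$post_srs[metrics$speed_condition == "quasistatic"] <- NA
rep <- build_report(list(metrics = metrics))
write_report(rep, file.path(out, "report"))
print(rep)

fr <- rep$friedman
w <- fr[fr$metric == "work" & fr$speed_condition == "dynamic", ]
message(sprintf(
  "\npreflex work vs perturbation (dynamic): p = %.3f / %.3f / %.3f at a = 0.05 / 0.15 / 0.25",
  w$p[w$activity == 0.05], w$p[w$activity == 0.15], w$p[w$activity == 0.25]))
message("report written to ", file.path(out, "report"))
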