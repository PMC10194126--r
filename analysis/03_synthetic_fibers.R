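#!/usr/bin/env Rscript
# Generate the synthetic skinned-fiber session: 9 fibers x 3 perturbations x
# 3 activity levels x 2 speed conditions, in randomized blocks bracketed by
# isometric reference contractions, with degradation and measurement noise.
#
# Usage: Rscript analysis/03_synthetic_fibers.R [results_dir] [seed]

library(preflexr)

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 1) args[1] else "results"
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

conds <- c(outer(c("up", "none", "down"), c("dynamic", "quasistatic"),
                 paste, sep = "."))
trajs <- lapply(conds, function(cond) {
  read_trajectory(file.path(out, sprintf("traj_%s.csv", cond)))
})
names(trajs) <- conds

session <- generate_experiment(trajs, n_fibers = 9,
                               activities = c(0.05, 0.15, 0.25),
                               seed = seed)
write_fiber_session(session, file.path(out, "session"))
man <- session$manifest
message(sprintf("session with %d trials (%d perturbation, %d reference) from seed %d",
                nrow(man), sum(man$kind == "perturbation"),
                sum(man$kind == "isometric_reference"), seed))
message("wrote per-trial CSVs and manifest under ", file.path(out, "session"))
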