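#!/usr/bin/env Rscript
# Simulate perturbed single-leg hopping and extract the contractile-element
# boundary conditions for the fiber experiments.
#
# Finds the periodic hopping limit cycle of the muscle-driven hopper, applies
# the three ground perturbations (5 cm step-up, none, 5 cm step-down), and
# writes per-scenario stride traces plus the dynamic (10 kHz) and 80x
# time-expanded quasistatic (1 kHz) CE trajectories used by every later stage.
#
# Usage: Rscript analysis/01_hopping_boundary_conditions.R [out_dir]

library(preflexr)

out <- commandArgs(trailingOnly = TRUE)
out <- if (length(out)) out[1] else "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- hopper_parameters()
message("searching the hopping limit cycle ...")
bc <- pipeline_trajectories(params)
lc <- bc$limit_cycle
leg <- leg_kinematics(params$phi_flight, params)$y
message(sprintf("limit cycle: apex %.3f m above contact after %d iterations",
                lc$h_apex - leg, lc$iterations))

summary_rows <- list()
for (sc in names(bc$strides)) {
  s <- bc$strides[[sc]]
  write.csv(s$trace, file.path(out, sprintf("stride_%s.csv", sc)),
            row.names = FALSE)
  px <- s$trace[s$trace$t_s <= params$t_px, ]
  summary_rows[[sc]] <- data.frame(
    scenario = sc,
    td_speed_m_s = s$td_speed,
    lce_norm_td = px$lce_norm[1],
    peak_vce_preflex = max(px$vce_norm_per_s),
    preflex_stretch = max(px$lce_norm) - px$lce_norm[1],
    stance_ms = 1000 * s$events[["to"]],
    energy_audit_J = s$energy_audit)
  message(sprintf(
    "%-5s: TD %.2f m/s | CE at TD %.3f l_opt | peak preflex vCE %.2f l_opt/s | stretch %.3f l_opt",
    sc, s$td_speed, px$lce_norm[1], max(px$vce_norm_per_s),
    max(px$lce_norm) - px$lce_norm[1]))
}
bc_summary <- do.call(rbind, summary_rows)
write.csv(bc_summary, file.path(out, "boundary_conditions.csv"),
          row.names = FALSE)

for (cond in names(bc$trajectories)) {
  write_trajectory(bc$trajectories[[cond]],
                   file.path(out, sprintf("traj_%s.csv", cond)))
}
message("the peak preflex stretch velocities across scenarios span ",
        sprintf("%.2f-%.2f l_opt/s (the in vitro protocol targets 3-5)",
                min(bc_summary$peak_vce_preflex),
                max(bc_summary$peak_vce_preflex)))
message("wrote strides, trajectories and boundary_conditions.csv to ", out)
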