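#' Boundary-condition trajectories for all conditions
#'
#' Simulates the three perturbation scenarios from one limit cycle, extracts
#' the stance lengthening profile of each, and derives the quasistatic
#' counterpart (80x time expansion, 1 kHz sampling).
#'
#' @param params [hopper_parameters()] object.
#' @param limit_cycle optional precomputed [find_limit_cycle()] result.
#' @param factor quasistatic time expansion factor (default 80).
#' @return list with `strides` (named list of `stride_result`) and
#'   `trajectories` (named list of [ce_trajectory()], names
#'   `"<scenario>.<speed>"`).
#' @export
pipeline_trajectories <- function(params, limit_cycle = NULL, factor = 80) {
  if (is.null(limit_cycle)) limit_cycle <- find_limit_cycle(params)
  scenarios <- c("up", "none", "down")
  strides <- lapply(scenarios, simulate_scenario, params = params,
                    limit_cycle = limit_cycle)
  names(strides) <- scenarios
  trajs <- list()
  for (sc in scenarios) {
    dyn <- extract_lengthening(strides[[sc]])
    trajs[[paste0(sc, ".dynamic")]] <- dyn
    trajs[[paste0(sc, ".quasistatic")]] <-
      make_quasistatic(dyn, factor = factor, fs = 1e3)
  }
  list(strides = strides, trajectories = trajs,
       limit_cycle = limit_cycle)
}

#' Run the full preflex pipeline
#'
#' End-to-end run: hopping limit cycle, perturbation scenarios, boundary
#' condition extraction (dynamic + quasistatic), isolated-CE simulations,
#' synthetic fiber session, preflex metrics, and the statistics report.
#' Identical `seed` (and parameters) reproduces identical outputs. The
#' single seed is fanned out to the per-stage seeds documented in the
#' manifest.
#'
#' @param seed integer master seed for the synthetic experiment.
#' @param out optional output directory; when given, stride and trajectory
#'   CSVs, the fiber session, `metrics.csv` and the report are written there.
#' @param params [hopper_parameters()] object (or path to a YAML config
#'   accepted by [read_mtu_config()]).
#' @param n_fibers,activities synthetic experiment design.
#' @param pop [fiber_population()] generator settings.
#' @return list with `strides`, `trajectories`, `isolated_ce` (list of force
#'   traces per condition x activity), `session`, `analysis` (metrics +
#'   work differences), and `report`.
#' @export
run_pipeline <- function(seed = 1, out = NULL,
                         params = hopper_parameters(),
                         n_fibers = 9,
                         activities = c(0.05, 0.15, 0.25),
                         pop = fiber_population()) {
  if (is.character(params)) {
    params <- read_mtu_config(params)
    if (!inherits(params, "hopper_parameters")) {
      stop("config file ", params, " has no HOPPER section")
    }
  }
  bc <- pipeline_trajectories(params)
  iso <- list()
  for (cond in names(bc$trajectories)) {
    for (a in activities) {
      iso[[paste(cond, a, sep = ".")]] <-
        simulate_isolated_ce(bc$trajectories[[cond]], a, params$mtu)
    }
  }
  session <- generate_experiment(bc$trajectories, n_fibers = n_fibers,
                                 activities = activities, seed = seed,
                                 pop = pop)
  analysis <- analyze_session(session, t_px = params$t_px)
  report <- build_report(analysis)
  out_list <- list(strides = bc$strides, trajectories = bc$trajectories,
                   limit_cycle = bc$limit_cycle,
                   isolated_ce = iso, session = session,
                   analysis = analysis, report = report, seed = seed)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (sc in names(bc$strides)) {
      utils::write.csv(bc$strides[[sc]]$trace,
                       file.path(out, sprintf("stride_%s.csv", sc)),
                       row.names = FALSE)
    }
    for (cond in names(bc$trajectories)) {
      write_trajectory(bc$trajectories[[cond]],
                       file.path(out, sprintf("traj_%s.csv", cond)))
    }
    write_fiber_session(session, file.path(out, "session"))
    utils::write.csv(analysis$metrics, file.path(out, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$work_diff, file.path(out, "work_diff.csv"),
                     row.names = FALSE)
    write_report(report, file.path(out, "report"))
    manifest <- list(seed = seed,
                     n_fibers = n_fibers, activities = activities,
                     apex_height_m = bc$limit_cycle$h_apex,
                     td_speeds_m_s = vapply(bc$strides, `[[`, 0, "td_speed"),
                     package_version =
                       as.character(utils::packageVersion("preflexr")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_list)
}
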