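#' Contractile-element kinematic trajectories
#'
#' A trajectory is the interchange object between the hopping simulation, the
#' isolated-CE simulation, and the synthetic fiber experiment: a data.frame
#' with columns `t_s` (strictly increasing, starting at 0), `lce_norm`
#' (CE length / l_opt), `vce_norm_per_s` (CE velocity / l_opt, lengthening
#' positive), `u` (stimulation), and the attributes `scenario`
#' (`"up"/"none"/"down"`) and `speed_condition` (`"dynamic"/"quasistatic"`).
#'
#' @param t_s,lce_norm,vce_norm_per_s,u trajectory columns.
#' @param scenario,speed_condition condition labels.
#' @return a `ce_trajectory` data.frame.
#' @export
ce_trajectory <- function(t_s, lce_norm, vce_norm_per_s, u,
                          scenario = "none", speed_condition = "dynamic") {
  stopifnot(length(t_s) == length(lce_norm),
            length(t_s) == length(vce_norm_per_s),
            all(diff(t_s) > 0))
  tr <- data.frame(t_s = t_s, lce_norm = lce_norm,
                   vce_norm_per_s = vce_norm_per_s,
                   u = rep_len(u, length(t_s)))
  attr(tr, "scenario") <- scenario
  attr(tr, "speed_condition") <- speed_condition
  class(tr) <- c("ce_trajectory", "data.frame")
  tr
}

#' Extract the preflex window of a stride
#'
#' Returns the CE kinematics over the first 30 ms of stance (the preflex
#' phase), resampled on a uniform 10 kHz grid by cubic spline interpolation
#' of the CE length with analytic differentiation for the velocity.
#'
#' @param stride a `stride_result` from [simulate_scenario()].
#' @param fs sampling rate \[Hz\] (default 10000).
#' @return a `ce_trajectory` spanning `[0, t_px]`; if stance is shorter than
#'   the preflex duration the trajectory is truncated at toe-off and carries
#'   the attribute `truncated = TRUE` (with a warning).
#' @export
extract_preflex <- function(stride, fs = 1e4) {
  stopifnot(inherits(stride, "stride_result"))
  t_px <- stride$params$t_px
  t_end <- min(t_px, stride$events[["to"]])
  truncated <- t_end < t_px
  if (truncated) {
    warning("stance shorter than the preflex duration; window truncated at toe-off")
  }
  out <- resample_trajectory(stride, 0, t_end, fs)
  attr(out, "truncated") <- truncated
  out
}

#' Extract the stance lengthening profile of a stride
#'
#' From touchdown to the maximal CE length (the lengthening part of the
#' stretch-shortening cycle), resampled at `fs`. This is the profile that is
#' replayed in the fiber experiments and expanded for the quasistatic
#' scenario, so that the matched-length analysis window can always be found.
#'
#' @inheritParams extract_preflex
#' @return a `ce_trajectory`.
#' @export
extract_lengthening <- function(stride, fs = 1e4) {
  stopifnot(inherits(stride, "stride_result"))
  tr <- stride$trace
  i_max <- which.max(tr$lce_norm)
  resample_trajectory(stride, 0, tr$t_s[i_max], fs)
}

resample_trajectory <- function(stride, t0, t1, fs) {
  tr <- stride$trace
  sp <- stats::splinefun(tr$t_s, tr$lce_norm, method = "natural")
  t_new <- seq(t0, t1, by = 1 / fs)
  u_new <- stats::approx(tr$t_s, tr$u, xout = t_new, rule = 2)$y
  ce_trajectory(t_s = t_new - t0,
                lce_norm = sp(t_new),
                vce_norm_per_s = sp(t_new, deriv = 1),
                u = u_new,
                scenario = stride$scenario,
                speed_condition = "dynamic")
}

#' Derive a quasistatic trajectory
#'
#' Expands the time base of a dynamic trajectory by `factor` (default 80)
#' while keeping the sequence of CE lengths identical, so every
#' path-dependent quantity (total stretch, force-length work at matched
#' samples) is unchanged and velocities scale down by `factor`. The result is
#' resampled at the quasistatic recording rate (default 1 kHz).
#'
#' @param traj a dynamic `ce_trajectory`.
#' @param factor time expansion factor (> 1; default 80).
#' @param fs output sampling rate \[Hz\]; `NULL` keeps the expanded sample
#'   instants unchanged (exact 1:1 mapping of the length values).
#' @return a `ce_trajectory` with `speed_condition = "quasistatic"` and
#'   provenance attributes `source_scenario` and `expansion_factor`.
#' @export
make_quasistatic <- function(traj, factor = 80, fs = NULL) {
  stopifnot(inherits(traj, "ce_trajectory"))
  if (factor < 1) stop("expansion factor must be >= 1")
  if (is.null(fs)) {
    out <- ce_trajectory(t_s = traj$t_s * factor,
                         lce_norm = traj$lce_norm,
                         vce_norm_per_s = traj$vce_norm_per_s / factor,
                         u = traj$u,
                         scenario = attr(traj, "scenario"),
                         speed_condition = if (factor == 1) {
                           attr(traj, "speed_condition")
                         } else "quasistatic")
  } else {
    t_new <- seq(0, max(traj$t_s) * factor, by = 1 / fs)
    sp <- stats::splinefun(traj$t_s * factor, traj$lce_norm,
                           method = "natural")
    out <- ce_trajectory(t_s = t_new,
                         lce_norm = sp(t_new),
                         vce_norm_per_s = sp(t_new, deriv = 1),
                         u = stats::approx(traj$t_s * factor, traj$u,
                                           xout = t_new, rule = 2)$y,
                         scenario = attr(traj, "scenario"),
                         speed_condition = "quasistatic")
  }
  attr(out, "source_scenario") <- attr(traj, "scenario")
  attr(out, "expansion_factor") <- factor
  out
}

#' Trajectory CSV input/output
#'
#' Writes/reads a trajectory as CSV with columns `t_s`, `lce_norm`,
#' `vce_norm_per_s`, `u`, `scenario`, `speed_condition` (UTF-8, '.' decimal,
#' full double precision). The reader tolerates extra columns (preserved as
#' additional data.frame columns) and reports the first offending row if time
#' is not strictly increasing.
#'
#' @param traj a `ce_trajectory`.
#' @param path file path.
#' @return `read_trajectory` returns a `ce_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ce_trajectory"))
  df <- as.data.frame(traj)
  df$scenario <- attr(traj, "scenario")
  df$speed_condition <- attr(traj, "speed_condition")
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "lce_norm", "vce_norm_per_s", "u",
            "scenario", "speed_condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trajectory file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad)) {
    stop("non-monotone time in ", path, " at row ", bad[1] + 1)
  }
  tr <- ce_trajectory(df$t_s, df$lce_norm, df$vce_norm_per_s, df$u,
                      scenario = df$scenario[1],
                      speed_condition = df$speed_condition[1])
  extra <- setdiff(names(df), need)
  for (cn in extra) tr[[cn]] <- df[[cn]]
  tr
}
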