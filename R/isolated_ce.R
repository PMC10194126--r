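#' Simulate the isolated contractile element
#'
#' Forward-simulates the CE + PEE (detached from the serial tendon elements)
#' under prescribed kinematics and a constant activity, mimicking the skinned
#' fiber preparation: the normalized force is the memoryless map
#' `F = (F_CE(l_CE, v_CE, a) + F_PEE(l_CE)) / F_max` evaluated at every
#' trajectory sample. There are no activation dynamics on this pathway
#' (stimulation and activity are identical, `u = a`), matching the chemical
#' activation of the in vitro preparation, which fixes one activity per
#' stretch-shortening cycle.
#'
#' @param traj a [ce_trajectory()].
#' @param a constant activity in (0, 1\]; typical presets are 0.05, 0.15,
#'   0.25.
#' @param params [mtu_parameters()] object.
#' @return a data.frame `t_s, lce_norm, vce_norm_per_s, f_norm` with the
#'   trajectory's condition attributes (`scenario`, `speed_condition`,
#'   `activity`) attached.
#' @export
simulate_isolated_ce <- function(traj, a, params) {
  stopifnot(inherits(traj, "ce_trajectory"))
  if (length(a) != 1 || a <= 0 || a > 1) {
    stop("activity must be a single value in (0, 1]")
  }
  f <- (ce_force(traj$lce_norm, traj$vce_norm_per_s, a, params) +
          parallel_elastic_force(traj$lce_norm, params)) / params$CE$F_max
  out <- data.frame(t_s = traj$t_s, lce_norm = traj$lce_norm,
                    vce_norm_per_s = traj$vce_norm_per_s, f_norm = f)
  attr(out, "scenario") <- attr(traj, "scenario")
  attr(out, "speed_condition") <- attr(traj, "speed_condition")
  attr(out, "activity") <- a
  out
}
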