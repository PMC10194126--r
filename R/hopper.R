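#' Leg kinematics of the two-segment hopper
#'
#' The hip sits above the foot at height `2 * l_seg * sin(phi / 2)` (two equal
#' segments, knee angle `phi` between them). The knee-extensor MTU length is
#' affine in the knee angle with constant moment arm `r`:
#' `l_MTU = l_MTU_ref + r * (phi_ref - phi)`.
#'
#' @param phi knee angle \[rad\] in (0, pi).
#' @param params [hopper_parameters()] object.
#' @return list with `y` (hip height above foot \[m\]), `l_MTU` \[m\], and
#'   `dphi_dy` (kinematic Jacobian \[rad/m\]).
#' @export
leg_kinematics <- function(phi, params) {
  if (any(phi <= 0 | phi >= pi)) stop("knee angle must lie in (0, pi)")
  list(y = 2 * params$l_seg * sin(phi / 2),
       l_MTU = params$l_MTU_ref + params$r * (params$phi_ref - phi),
       dphi_dy = 1 / (params$l_seg * cos(phi / 2)))
}

knee_angle_from_height <- function(y_rel, params) {
  x <- y_rel / (2 * params$l_seg)
  if (any(x >= 1)) stop("leg over-extension: hip height exceeds leg length")
  if (any(x <= 0)) stop("leg over-flexion: hip at ground level")
  2 * asin(x)
}

#' Stimulation profile over a stance phase
#'
#' Constant `u0` during the 30 ms preflex phase, then a linear ramp with slope
#' `b` saturating at 1: `u = min(1, u0 + b * (t - t_px))`.
#'
#' @param t_since_TD time since touchdown \[s\] (>= 0); vectorized.
#' @param params [hopper_parameters()] object.
#' @return stimulation in \[0, 1\].
#' @export
stimulation_profile <- function(t_since_TD, params) {
  stopifnot(all(t_since_TD >= 0))
  pmin(1, params$u0 + params$b * pmax(t_since_TD - params$t_px, 0))
}

# MTU force on the serial side for a given internal state; also returns the
# solved CE velocity. Used by both flight (v_MTU = 0) and stance dynamics.
mtu_force_and_vce <- function(l_CE, a, l_MTU, v_MTU, mtu) {
  v_CE <- ce_contraction_velocity(l_CE, a, l_MTU, v_MTU, mtu)
  l_norm <- l_CE / mtu$CE$l_opt
  f_con <- ce_force(l_norm, v_CE / mtu$CE$l_opt, a, mtu) +
    parallel_elastic_force(l_norm, mtu)
  f_mtu <- serial_elastic_force(l_MTU - l_CE, mtu) +
    serial_damping_coefficient(f_con, mtu) * (v_MTU - v_CE)
  list(v_CE = v_CE, F_MTU = f_mtu, f_con = f_con)
}

#' Simulate the flight phase
#'
#' Ballistic motion of the point mass with the knee locked at `phi_flight`.
#' The MTU length is fixed; the internal CE state keeps evolving toward the
#' CE/SEE equilibrium under constant stimulation `u0`. Integration stops at
#' the touchdown event, where the foot (hip height minus leg length) meets the
#' ground.
#'
#' @param state named vector with `y` (hip height \[m\], absolute), `vy`
#'   \[m/s\], `l_CE` \[m\], `a`.
#' @param ground_height ground level \[m\] (0 = unperturbed).
#' @param params [hopper_parameters()] object.
#' @param t0 start time \[s\].
#' @return list with `state_td` (state at touchdown), `t_td`, and the flight
#'   `trace` (data.frame).
#' @export
simulate_flight <- function(state, ground_height, params, t0 = 0) {
  mtu <- params$mtu
  lk <- leg_kinematics(params$phi_flight, params)
  leg_len <- lk$y
  l_MTU <- lk$l_MTU
  if (state[["y"]] <= ground_height + leg_len && state[["vy"]] <= 0) {
    stop("flight start is already at or below ground contact")
  }
  deriv <- function(t, s, p) {
    a <- clamp01(s[["a"]], mtu)
    res <- mtu_force_and_vce(s[["l_CE"]], a, l_MTU, 0, mtu)
    da <- (activation_stationary(params$u0, mtu) - a) / mtu$ACT$tau_act
    list(c(s[["vy"]], -params$g, res$v_CE, da))
  }
  rootf <- function(t, s, p) s[["y"]] - (ground_height + leg_len)
  y0 <- c(y = state[["y"]], vy = state[["vy"]],
          l_CE = state[["l_CE"]], a = state[["a"]])
  # generous horizon; the root function terminates at touchdown
  t_max <- t0 + 2 * (abs(state[["vy"]]) / params$g +
                       sqrt(2 * max(state[["y"]] - ground_height - leg_len,
                                    1e-6) / params$g)) + 0.5
  times <- seq(t0, t_max, by = 1e-3)
  sol <- deSolve::lsodar(y0, times, deriv, parms = NULL,
                         rtol = params$rtol, atol = params$atol,
                         rootfunc = rootf)
  tr <- as.data.frame(sol)
  if (is.null(attr(sol, "troot")) || length(attr(sol, "troot")) == 0) {
    stop("flight trajectory never reached the ground")
  }
  last <- tr[nrow(tr), ]
  list(state_td = c(y = last$y, vy = last$vy, l_CE = last$l_CE, a = last$a),
       t_td = last$time, trace = tr)
}

#' Simulate the stance phase
#'
#' Point-mass dynamics `m * y'' = GRF - m * g` with the ground reaction force
#' obtained by virtual work on the massless leg, `GRF = F_MTU * r * dphi/dy`.
#' The MTU contraction and activation dynamics are integrated concurrently;
#' stimulation follows [stimulation_profile()]. Stance ends at the first
#' downward zero crossing of the GRF (toe-off). A work integral
#' `dW/dt = GRF * vy` is carried along for the energy audit.
#'
#' @param state_td named state at touchdown (`y`, `vy`, `l_CE`, `a`).
#' @param ground_height ground level \[m\].
#' @param params [hopper_parameters()] object.
#' @param t_td absolute touchdown time \[s\].
#' @param dt output sampling interval \[s\] (default 1e-4, i.e. 10 kHz).
#' @return list with `trace` (data.frame: time, y, vy, phi, lce_norm,
#'   vce_norm, u, a, grf, work), `t_to` (toe-off time) and `state_to`.
#' @export
simulate_stance <- function(state_td, ground_height, params, t_td = 0,
                            dt = 1e-4) {
  mtu <- params$mtu
  deriv_core <- function(t, s) {
    y_rel <- s[["y"]] - ground_height
    phi <- knee_angle_from_height(y_rel, params)
    lk <- leg_kinematics(phi, params)
    a <- clamp01(s[["a"]], mtu)
    v_MTU <- -params$r * lk$dphi_dy * s[["vy"]]
    res <- mtu_force_and_vce(s[["l_CE"]], a, lk$l_MTU, v_MTU, mtu)
    grf <- res$F_MTU * params$r * lk$dphi_dy
    u <- stimulation_profile(max(t - t_td, 0), params)
    da <- (activation_stationary(u, mtu) - a) / mtu$ACT$tau_act
    list(d = c(s[["vy"]], grf / params$m - params$g, res$v_CE, da,
               grf * s[["vy"]]),
         grf = grf, u = u, v_CE = res$v_CE, phi = phi)
  }
  deriv <- function(t, s, p) {
    r <- deriv_core(t, s)
    list(r$d, grf = r$grf, u = r$u,
         lce_norm = s[["l_CE"]] / mtu$CE$l_opt,
         vce_norm = r$v_CE / mtu$CE$l_opt,
         phi = r$phi)
  }
  rootf <- function(t, s, p) deriv_core(t, s)$grf
  y0 <- c(y = state_td[["y"]], vy = state_td[["vy"]],
          l_CE = state_td[["l_CE"]], a = state_td[["a"]], work = 0)
  r0 <- deriv_core(t_td, y0)
  if (r0$grf < 0) stop("GRF negative at touchdown")
  times <- seq(t_td, t_td + 1.5, by = dt)
  sol <- deSolve::lsodar(y0, times, deriv, parms = NULL,
                         rtol = params$rtol, atol = params$atol,
                         rootfunc = rootf)
  if (is.null(attr(sol, "troot")) || length(attr(sol, "troot")) == 0) {
    stop("stance never reached toe-off (GRF did not return to zero)")
  }
  tr <- as.data.frame(sol)
  last <- tr[nrow(tr), ]
  list(trace = tr, t_to = last$time,
       state_to = c(y = last$y, vy = last$vy, l_CE = last$l_CE, a = last$a),
       work = last$work)
}

#' Find the periodic hopping limit cycle
#'
#' Fixed-point iteration on the apex-to-apex return map: starting from an
#' apex state (zero vertical velocity, knee locked, internal state at the
#' flight equilibrium), one full cycle (flight, stance, flight to apex) is
#' simulated and the apex height updated until two successive apex heights
#' differ by less than `apex_tol`.
#'
#' @param params [hopper_parameters()] object.
#' @param h_apex0 initial apex hip height \[m\]; default: leg length at the
#'   flight knee angle + 5 cm.
#' @param max_iter maximal number of return-map iterations.
#' @return list with `state_apex` (converged apex state), `h_apex`, and
#'   `history` (apex heights per iteration).
#' @export
find_limit_cycle <- function(params, h_apex0 = NULL, max_iter = 60) {
  leg_len <- leg_kinematics(params$phi_flight, params)$y
  if (is.null(h_apex0)) h_apex0 <- leg_len + 0.05
  mtu <- params$mtu
  a_eq <- activation_stationary(params$u0, mtu)
  l_ce_eq <- flight_equilibrium_l_ce(params)
  state <- c(y = h_apex0, vy = 0, l_CE = l_ce_eq, a = a_eq)
  history <- numeric(0)
  for (i in seq_len(max_iter)) {
    nxt <- hop_cycle(state, 0, params)
    history <- c(history, nxt$h_apex)
    if (abs(nxt$h_apex - state[["y"]]) < params$apex_tol) {
      return(list(state_apex = nxt$state_apex, h_apex = nxt$h_apex,
                  history = history, iterations = i))
    }
    state <- nxt$state_apex
  }
  stop("limit-cycle search did not converge; apex history: ",
       paste(sprintf("%.5f", history), collapse = ", "))
}

# CE length at the flight CE/SEE equilibrium (v = 0, a stationary at u0).
flight_equilibrium_l_ce <- function(params) {
  mtu <- params$mtu
  a <- activation_stationary(params$u0, mtu)
  l_MTU <- leg_kinematics(params$phi_flight, params)$l_MTU
  f <- function(l_CE) {
    l_norm <- l_CE / mtu$CE$l_opt
    ce_force(l_norm, 0, a, mtu) + parallel_elastic_force(l_norm, mtu) -
      serial_elastic_force(l_MTU - l_CE, mtu)
  }
  lo <- 0.2 * mtu$CE$l_opt
  hi <- min(1.6 * mtu$CE$l_opt, l_MTU - 1e-9)
  stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
}

# One apex-to-apex hop: flight down, stance, and closed-form ballistic apex
# from the toe-off state (flight is ballistic, so the apex follows exactly).
hop_cycle <- function(state_apex, ground_height, params) {
  fl <- simulate_flight(state_apex, ground_height, params, t0 = 0)
  st <- simulate_stance(fl$state_td, ground_height, params, t_td = fl$t_td)
  s <- st$state_to
  h_apex <- s[["y"]] + s[["vy"]]^2 / (2 * params$g)
  t_apex_rel <- s[["vy"]] / params$g
  # internal state keeps relaxing toward the flight equilibrium during ascent
  mtu <- params$mtu
  a_ap <- activation_stationary(params$u0, mtu) +
    (s[["a"]] - activation_stationary(params$u0, mtu)) *
    exp(-t_apex_rel / mtu$ACT$tau_act)
  l_MTU <- leg_kinematics(params$phi_flight, params)$l_MTU
  l_ce_ap <- relax_ce(s[["l_CE"]], s[["a"]], a_ap, l_MTU, t_apex_rel, params)
  list(state_apex = c(y = h_apex, vy = 0, l_CE = l_ce_ap, a = a_ap),
       h_apex = h_apex, flight = fl, stance = st)
}

# integrate the CE state at fixed MTU length over a time span (knee locked)
relax_ce <- function(l_CE0, a0, a1, l_MTU, t_span, params) {
  if (t_span <= 0) return(l_CE0)
  mtu <- params$mtu
  deriv <- function(t, s, p) {
    a_t <- activation_stationary(params$u0, mtu) +
      (a0 - activation_stationary(params$u0, mtu)) * exp(-t / mtu$ACT$tau_act)
    list(ce_contraction_velocity(s[["l_CE"]], a_t, l_MTU, 0, mtu))
  }
  sol <- deSolve::lsoda(c(l_CE = l_CE0), c(0, t_span), deriv, parms = NULL,
                        rtol = params$rtol, atol = params$atol)
  unname(sol[nrow(sol), "l_CE"])
}

#' Simulate one perturbed hopping stride
#'
#' From the converged limit-cycle apex, the ground under the hopper is
#' shifted by `+dh` (step-up, `"up"`), `0` (`"none"`), or `-dh` (step-down,
#' `"down"`), and one full stride (flight to touchdown, stance to toe-off) is
#' simulated. Time is re-referenced so touchdown is `t = 0`.
#'
#' @param scenario one of `"up"`, `"none"`, `"down"`.
#' @param params [hopper_parameters()] object.
#' @param limit_cycle optional result of [find_limit_cycle()] (recomputed if
#'   missing).
#' @return an object of class `stride_result`: list with `trace` (stance
#'   data.frame: t_s from touchdown, y_m, ydot_m_s, phi_rad, lce_norm,
#'   vce_norm_per_s, u, a, grf_N), `events` (named times: td, preflex_end,
#'   to), `scenario`, `td_speed`, `flight_trace`, and `energy_audit`
#'   (|Delta(KE+PE) - int GRF vy dt| over stance, J).
#' @export
simulate_scenario <- function(scenario = c("none", "up", "down"), params,
                              limit_cycle = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(limit_cycle)) limit_cycle <- find_limit_cycle(params)
  ground <- switch(scenario, up = params$dh, none = 0, down = -params$dh)
  fl <- simulate_flight(limit_cycle$state_apex, ground, params, t0 = 0)
  st <- simulate_stance(fl$state_td, ground, params, t_td = fl$t_td)
  tr <- st$trace
  tr$time <- tr$time - fl$t_td
  names(tr) <- sub("^time$", "t_s", names(tr))
  out <- data.frame(t_s = tr$t_s, y_m = tr$y, ydot_m_s = tr$vy,
                    phi_rad = tr$phi, lce_norm = tr$lce_norm,
                    vce_norm_per_s = tr$vce_norm, u = tr$u, a = tr$a,
                    grf_N = tr$grf)
  m <- params$m; g <- params$g
  e0 <- 0.5 * m * tr$vy[1]^2 + m * g * tr$y[1]
  e1 <- 0.5 * m * tr$vy[nrow(tr)]^2 + m * g * tr$y[nrow(tr)]
  audit <- abs((e1 - e0) - st$work)
  res <- list(trace = out,
              events = c(td = 0, preflex_end = params$t_px,
                         to = st$t_to - fl$t_td),
              scenario = scenario,
              td_speed = abs(fl$state_td[["vy"]]),
              ground_height = ground,
              flight_trace = fl$trace,
              energy_audit = audit,
              params = params)
  class(res) <- "stride_result"
  res
}

#' @export
print.stride_result <- function(x, ...) {
  cat(sprintf(
    "<stride_result> scenario=%s  TD speed %.3f m/s  stance %.0f ms  peak vCE %.2f l_opt/s\n",
    x$scenario, x$td_speed, 1000 * x$events[["to"]],
    max(x$trace$vce_norm_per_s)))
  invisible(x)
}

# keep the activity state inside [a_min, 1] against integrator overshoot
clamp01 <- function(a, mtu) min(max(a, mtu$ACT$a_min), 1)
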