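#' Normalized isometric force-length relation
#'
#' Bell-shaped force-length curve of the contractile element,
#' `F_isom = exp(-|(l_norm - 1) / dW|^nu)`, with independent width and
#' exponent for the ascending (`l_norm < 1`) and descending (`l_norm > 1`)
#' limbs.
#'
#' @param l_norm CE length normalized by `l_opt` (> 0); vectorized.
#' @param params [mtu_parameters()] object.
#' @return normalized isometric force in \[0, 1\].
#' @export
isom_force_length <- function(l_norm, params) {
  stopifnot(all(l_norm > 0))
  ce <- params$CE
  dW <- ifelse(l_norm < 1, ce$dW_asc, ce$dW_des)
  nu <- ifelse(l_norm < 1, ce$nu_asc, ce$nu_des)
  exp(-abs((l_norm - 1) / dW)^nu)
}

# Effective Hill parameters at a given length/activity.
# A_rel scales with (1 + 3a)/4 and, on the descending limb, with F_isom;
# B_rel scales with (3 + 4a)/7.  Both scalings can be switched off
# (fv_act_dependence = FALSE) for constant A_rel0, B_rel0.
hill_arel_brel <- function(l_norm, a, params) {
  ce <- params$CE
  if (ce$fv_act_dependence) {
    L_A <- ifelse(l_norm < 1, 1, isom_force_length(l_norm, params))
    A_rel <- ce$A_rel0 * L_A * (1 + 3 * a) / 4
    B_rel <- ce$B_rel0 * (3 + 4 * a) / 7
  } else {
    A_rel <- rep_len(ce$A_rel0, length(l_norm))
    B_rel <- rep_len(ce$B_rel0, length(l_norm))
  }
  list(A_rel = A_rel, B_rel = B_rel)
}

#' Contractile element force
#'
#' Hill force-velocity relation of the CE. Lengthening velocities are
#' positive. The concentric branch (`v_norm <= 0`) is the classic Hill
#' hyperbola through the isometric point `(0, a * F_isom * F_max)` and the
#' maximal shortening velocity (force clamped at zero beyond it). The
#' eccentric branch (`v_norm > 0`) is
#' `F_CE = F_max * ((a * F_isom + A_rel_e) / (1 - v_norm / B_rel_e) - A_rel_e)`
#' with `A_rel_e`, `B_rel_e` (both negative) derived internally from three
#' conditions: force continuity at zero velocity, slope ratio `S_e` between
#' the eccentric and concentric branch at zero velocity, and the eccentric
#' plateau `F_e * a * F_isom * F_max` as `v_norm -> Inf`.
#'
#' @param l_norm CE length \[l_opt\].
#' @param v_norm CE velocity \[l_opt/s\], lengthening positive; vectorized.
#' @param a activity in \[0, 1\].
#' @param params [mtu_parameters()] object.
#' @return CE force \[N\].
#' @export
ce_force <- function(l_norm, v_norm, a, params) {
  stopifnot(all(l_norm > 0))
  if (any(a < 0 | a > 1)) stop("activity must lie in [0, 1]")
  ce <- params$CE
  n <- max(length(l_norm), length(v_norm))
  l_norm <- rep_len(l_norm, n); v_norm <- rep_len(v_norm, n)
  a <- rep_len(a, n)
  F_isom <- isom_force_length(l_norm, params)
  hp <- hill_arel_brel(l_norm, a, params)
  q <- a * F_isom                       # normalized isometric operating force
  out <- numeric(n)

  conc <- v_norm <= 0
  if (any(conc)) {
    f <- (q[conc] + hp$A_rel[conc]) /
      (1 - v_norm[conc] / hp$B_rel[conc]) - hp$A_rel[conc]
    out[conc] <- pmax(f, 0)
  }
  ecc <- !conc
  if (any(ecc)) {
    qe <- q[ecc]
    tiny <- qe <= .Machine$double.eps
    A_e <- -params$CE$F_e * qe
    # slope continuity: eccentric slope at v = 0 equals S_e x concentric slope
    B_e <- hp$B_rel[ecc] * qe * (1 - ce$F_e) /
      (ce$S_e * (qe + hp$A_rel[ecc]))
    f <- (qe + A_e) / (1 - v_norm[ecc] / B_e) - A_e
    f[tiny] <- 0
    out[ecc] <- f
  }
  params$CE$F_max * out
}

#' Parallel elastic element force
#'
#' Power-law spring engaged above its rest length `L_PEE0 * l_opt`:
#' `F_PEE = K_PEE * (l_CE - L_PEE0 * l_opt)^nu_PEE`, zero (slack) below.
#'
#' @inheritParams ce_force
#' @return PEE force \[N\]; vectorized over `l_norm`.
#' @export
parallel_elastic_force <- function(l_norm, params) {
  stopifnot(all(l_norm > 0))
  pe <- params$PEE
  dl <- pmax(l_norm - pe$L_PEE0, 0) * params$CE$l_opt
  pe$K_PEE * dl^pe$nu_PEE
}

#' Serial elastic + serial damping force
#'
#' The SEE is slack below its rest length, rises as a power law
#' (exponent `dU_SEE_nll / dU_SEE_l`) up to the strain `dU_SEE_nll`, and is
#' linear above; value and slope are continuous at the transition. The SDE is
#' a linear damper whose coefficient scales with the load on the contractile
#' side: `d = d_SE_max * ((1 - R_SE) * f_load / F_max + R_SE)`.
#'
#' @param l_SEE SEE length \[m\] (>= 0).
#' @param v_SEE SEE lengthening velocity \[m/s\].
#' @param f_load force on the contractile side (CE + PEE) \[N\], used for the
#'   load-dependent damping coefficient.
#' @param params [mtu_parameters()] object.
#' @return total serial force SEE + SDE \[N\].
#' @export
serial_element_force <- function(l_SEE, v_SEE, f_load, params) {
  if (any(l_SEE < 0)) stop("SEE length must be non-negative")
  serial_elastic_force(l_SEE, params) +
    serial_damping_coefficient(f_load, params) * v_SEE
}

serial_elastic_force <- function(l_SEE, params) {
  s <- params$SEE
  dl <- l_SEE - s$l_SEE0
  dl_nll <- s$dU_SEE_nll * s$l_SEE0
  ifelse(dl <= 0, 0,
         ifelse(dl < dl_nll,
                s$K_SEE_nl * dl^s$nu_SEE,
                s$dF_SEE0 + s$K_SEE_l * (dl - dl_nll)))
}

serial_damping_coefficient <- function(f_load, params) {
  sd <- params$SDE
  sd$d_SE_max * ((1 - sd$R_SE) * f_load / params$CE$F_max + sd$R_SE)
}

#' Contraction dynamics: solve for the CE velocity
#'
#' The CE velocity follows from the instantaneous force balance between the
#' contractile side (CE + PEE) and the serial side (SEE + SDE) of the MTU:
#' `F_CE(l_CE, v_CE, a) + F_PEE(l_CE) = F_SEE(l_MTU - l_CE) +
#' F_SDE(v_MTU - v_CE)`. The residual is strictly increasing in `v_CE`
#' (the CE force rises with lengthening velocity, the damper force falls), so
#' the root is unique; it is bracketed and found with [stats::uniroot()], then
#' polished so the residual is below `1e-10 * F_max`.
#'
#' @param l_CE CE length \[m\].
#' @param a activity in \[0, 1\].
#' @param l_MTU MTU length \[m\] (must satisfy `l_MTU >= l_CE`).
#' @param v_MTU MTU lengthening velocity \[m/s\].
#' @param params [mtu_parameters()] object.
#' @return CE velocity \[m/s\], lengthening positive.
#' @export
ce_contraction_velocity <- function(l_CE, a, l_MTU, v_MTU, params,
                                    method = c("closed_form", "uniroot")) {
  method <- match.arg(method)
  ce <- params$CE
  l_norm <- l_CE / ce$l_opt
  l_SEE <- l_MTU - l_CE
  if (l_SEE < 0) stop("SEE length negative: l_MTU < l_CE")
  f_par <- parallel_elastic_force(l_norm, params)
  f_see <- serial_elastic_force(l_SEE, params)
  resid <- function(v) {
    f_con <- ce_force(l_norm, v / ce$l_opt, a, params) + f_par
    f_con - f_see -
      serial_damping_coefficient(f_con, params) * (v_MTU - v)
  }
  if (method == "closed_form") {
    v <- ce_velocity_closed_form(l_norm, a, f_par, f_see, v_MTU, params)
    if (!is.null(v) && is.finite(v) && abs(resid(v)) < 1e-10 * ce$F_max) {
      return(v)
    }
    # fall through to the bracketing solver on any degenerate case
  }
  # bracket: start from the concentric zero-force velocity and one optimal
  # length per second eccentric, expand downward if needed
  hp <- hill_arel_brel(l_norm, a, params)
  q <- a * isom_force_length(l_norm, params)
  v_conc0 <- -hp$B_rel * q / hp$A_rel * ce$l_opt   # F_CE = 0 (shortening)
  lo <- min(v_conc0 * 2 - ce$l_opt, v_MTU - ce$l_opt)
  hi <- max(2 * ce$l_opt, v_MTU + 2 * ce$l_opt)
  for (k in 1:60) {
    if (resid(lo) <= 0) break
    lo <- lo * 2 - ce$l_opt
  }
  for (k in 1:60) {
    if (resid(hi) >= 0) break
    hi <- hi * 2 + ce$l_opt
  }
  if (resid(lo) > 0 || resid(hi) < 0) {
    stop(sprintf(paste0("no admissible CE velocity root ",
                        "(l_CE = %.6g m, a = %.4g, l_MTU = %.6g m, ",
                        "v_MTU = %.6g m/s)"), l_CE, a, l_MTU, v_MTU))
  }
  r <- stats::uniroot(resid, c(lo, hi), tol = 1e-14)
  v <- r$root
  # Newton polish on the smooth branch to push the residual below 1e-10 F_max
  for (k in 1:8) {
    fv <- resid(v)
    if (abs(fv) < 1e-10 * ce$F_max) break
    h <- 1e-7 * max(abs(v), ce$l_opt)
    dfv <- (resid(v + h) - resid(v - h)) / (2 * h)
    if (!is.finite(dfv) || dfv <= 0) break
    v <- v - fv / dfv
  }
  v
}

# Closed-form solution of the CE velocity force balance.  On either Hill
# branch the balance is quadratic in x = 1 - v_n/B: with
# F_CE = F_max ((q + A)/x - A), f_con = C1/x + C0 and the load-dependent
# damper d(f_con) = D1 f_con + D0, multiplying the balance by x gives
#   a2 x^2 + a1 x + a0 = 0,
#   a2 = -(D1 C0 + D0) B l_opt
#   a1 = C0 - f_see - D1 C1 B l_opt - (D1 C0 + D0) (v_MTU - B l_opt)
#   a0 = C1 (1 - D1 (v_MTU - B l_opt)).
# The branch is picked from the sign of the residual at v = 0; beyond the
# maximal shortening velocity the CE force is clamped at zero and the
# balance is linear.  Returns NULL when no admissible root is found (the
# caller falls back to the bracketing solver).
ce_velocity_closed_form <- function(l_norm, a, f_par, f_see, v_MTU, params) {
  ce <- params$CE
  F_max <- ce$F_max; l_opt <- ce$l_opt
  dmax <- params$SDE$d_SE_max; R <- params$SDE$R_SE
  D1 <- dmax * (1 - R) / F_max; D0 <- dmax * R
  q <- a * isom_force_length(l_norm, params)
  hp <- hill_arel_brel(l_norm, a, params)
  dcoef <- function(f) D1 * f + D0
  f0 <- F_max * q + f_par
  g0 <- f0 - f_see - dcoef(f0) * v_MTU
  if (abs(g0) < 1e-12 * F_max) return(0)
  if (g0 < 0) {                       # eccentric branch
    if (q <= .Machine$double.eps) return(NULL)
    A <- -ce$F_e * q
    B <- hp$B_rel * q * (1 - ce$F_e) / (ce$S_e * (q + hp$A_rel))
    lo <- 0; hi <- Inf
  } else {                            # concentric branch
    A <- hp$A_rel; B <- hp$B_rel
    lo <- -B * l_opt * q / A; hi <- 0
  }
  C1 <- F_max * (q + A); C0 <- -F_max * A + f_par
  w <- v_MTU - B * l_opt
  a2 <- -(D1 * C0 + D0) * B * l_opt
  a1 <- C0 - f_see - D1 * C1 * B * l_opt - (D1 * C0 + D0) * w
  a0 <- C1 * (1 - D1 * w)
  v <- NULL
  if (abs(a2) < .Machine$double.eps * max(abs(a1), 1)) {
    if (a1 != 0) v <- B * l_opt * (1 + a0 / a1)
  } else {
    disc <- a1^2 - 4 * a2 * a0
    if (disc >= 0) {
      xs <- c((-a1 + sqrt(disc)) / (2 * a2), (-a1 - sqrt(disc)) / (2 * a2))
      vs <- B * l_opt * (1 - xs)
      tol <- 1e-9 * l_opt
      # x > 0 selects the hyperbola branch through the isometric point
      ok <- xs > 0 & vs >= lo - tol & vs <= hi + tol
      if (any(ok)) v <- min(max(vs[ok][1], lo), hi)
    }
  }
  if (is.null(v) && g0 > 0) {
    # clamped region: F_CE = 0 faster than the maximal shortening velocity
    d_par <- dcoef(f_par)
    if (d_par > 0) {
      v_lin <- v_MTU - (f_par - f_see) / d_par
      if (v_lin <= lo + 1e-9 * l_opt) v <- v_lin
    }
  }
  v
}

#' One step of the activation dynamics
#'
#' First-order lag of the activity behind the neural stimulation:
#' `da/dt = (u - a) / tau_act`, integrated exactly over `dt` and clamped to
#' `[a_min, 1]`. The isolated contractile element pathway bypasses this
#' operation entirely (there `u = a` by construction).
#'
#' @param u stimulation in \[0, 1\].
#' @param a current activity.
#' @param dt time step \[s\] (> 0).
#' @param params [mtu_parameters()] object.
#' @return activity after `dt`.
#' @export
activation_step <- function(u, a, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(u >= 0, u <= 1, a >= 0, a <= 1)
  target <- activation_stationary(u, params)
  a_new <- target + (a - target) * exp(-dt / params$ACT$tau_act)
  min(max(a_new, params$ACT$a_min), 1)
}

#' Stationary activity for a constant stimulation
#'
#' @inheritParams activation_step
#' @return the activity reached as `t -> Inf` under constant `u`.
#' @export
activation_stationary <- function(u, params) {
  min(max(u, params$ACT$a_min), 1)
}

#' Fit the ascending limb of the force-length curve
#'
#' Least-squares fit of the bell-curve ascending limb
#' `F = exp(-((1 - l_norm) / dW_asc)^nu_asc)` to (length, force) pairs with
#' `l_norm < 1`, as done when matching the model's force-length relation to
#' measured fiber data.
#'
#' @param l_norm normalized lengths (only points with `l_norm < 1` are used).
#' @param force normalized forces in \[0, 1\].
#' @param start optional named start values `c(dW_asc = , nu_asc = )`.
#' @return a list with `dW_asc`, `nu_asc`, `rss` (residual sum of squares) and
#'   `fitted`.
#' @export
fit_force_length_ascending <- function(l_norm, force,
                                       start = c(dW_asc = 0.5, nu_asc = 2)) {
  keep <- l_norm < 1
  l <- l_norm[keep]; f <- force[keep]
  if (length(l) < 3) stop("need at least 3 points on the ascending limb")
  if (stats::sd(f) < .Machine$double.eps^0.5) {
    stop("degenerate data: forces on the ascending limb are constant, ",
         "(dW_asc, nu_asc) not identifiable")
  }
  obj <- function(th) {
    dW <- exp(th[1]); nu <- 1 + exp(th[2])
    sum((f - exp(-((1 - l) / dW)^nu))^2)
  }
  th0 <- c(log(start[["dW_asc"]]), log(start[["nu_asc"]] - 1 + 1e-8))
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  dW <- exp(opt$par[1]); nu <- 1 + exp(opt$par[2])
  rss0 <- obj(th0)
  list(dW_asc = dW, nu_asc = nu, rss = opt$value,
       rss_start = rss0,
       fitted = exp(-((1 - l) / dW)^nu))
}
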