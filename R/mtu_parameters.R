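#' Muscle-tendon unit parameters
#'
#' Builds the parameter set of the four-element Hill-type muscle-tendon unit
#' (MTU): contractile element (CE) with force-length and force-velocity
#' relations, parallel elastic element (PEE), serial elastic element (SEE),
#' serial damping element (SDE), and first-order activation dynamics.
#'
#' Sign convention used throughout the package: a *positive* CE velocity is
#' *lengthening* (eccentric); shortening velocities are negative. This is
#' stated prominently because much of the Hill-model literature uses the
#' opposite convention.
#'
#' The default numeric values are reconstructions in the spirit of the
#' classical four-element model family (dimensionless shape constants, SI
#' units elsewhere); they are configuration, not physical constants, and every
#' one of them can be overridden.
#'
#' @param F_max maximal isometric CE force \[N\].
#' @param l_opt CE optimal length \[m\].
#' @param dW_asc,dW_des widths of the ascending/descending limb of the
#'   isometric force-length bell curve \[l_opt\].
#' @param nu_asc,nu_des exponents of the ascending/descending limb
#'   (dimensionless, >= 1).
#' @param A_rel0 normalized Hill force parameter (dimensionless, > 0).
#' @param B_rel0 normalized Hill velocity parameter \[1/s\].
#' @param S_e ratio of the eccentric to the concentric force-velocity slope at
#'   zero velocity (dimensionless, > 1).
#' @param F_e eccentric force plateau as a multiple of the isometric force at
#'   the current length and activity (dimensionless, > 1).
#' @param fv_act_dependence if `TRUE` (default) the Hill parameters A_rel and
#'   B_rel scale with activity and CE length as in the classical model family;
#'   if `FALSE` they are held at `A_rel0`, `B_rel0` (useful in unit tests).
#' @param L_PEE0 PEE rest length \[l_opt\].
#' @param nu_PEE PEE exponent (dimensionless).
#' @param F_PEE PEE force at the end of the descending force-length limb
#'   \[F_max\].
#' @param l_SEE0 SEE rest length \[m\].
#' @param dU_SEE_nll SEE strain at the nonlinear-to-linear transition
#'   (dimensionless).
#' @param dU_SEE_l SEE strain increment over which force rises by
#'   `dF_SEE0` in the linear region (dimensionless).
#' @param dF_SEE0 SEE force at the nonlinear-to-linear transition \[N\];
#'   default `0.4 * F_max`.
#' @param D_SE dimensionless SDE damping coefficient; the maximal damping is
#'   `d_SE_max = D_SE * F_max * A_rel0 / (l_opt * B_rel0)`.
#' @param R_SE minimal (zero-load) fraction of the SDE damping coefficient.
#' @param tau_act activation time constant \[s\].
#' @param a_min minimal activity (dimensionless, in \[0, 1)).
#'
#' @return an object of class `mtu_parameters`: a named list with components
#'   `CE`, `PEE`, `SEE`, `SDE`, `ACT` plus derived constants (`K_PEE`,
#'   `K_SEE_nl`, `K_SEE_l`, `nu_SEE`, `d_SE_max`).
#' @export
mtu_parameters <- function(F_max = 30000,
                           l_opt = 0.10,
                           dW_asc = 0.45, nu_asc = 1.5,
                           dW_des = 0.32, nu_des = 1.54,
                           A_rel0 = 0.25, B_rel0 = 3.0,
                           S_e = 2.0, F_e = 1.5,
                           fv_act_dependence = TRUE,
                           L_PEE0 = 0.9, nu_PEE = 2.5, F_PEE = 2.0,
                           l_SEE0 = 0.40,
                           dU_SEE_nll = 0.0425, dU_SEE_l = 0.017,
                           dF_SEE0 = 0.4 * F_max,
                           D_SE = 0.3, R_SE = 0.01,
                           tau_act = 0.01, a_min = 0.005) {
  p <- list(
    CE = list(F_max = F_max, l_opt = l_opt,
              dW_asc = dW_asc, nu_asc = nu_asc,
              dW_des = dW_des, nu_des = nu_des,
              A_rel0 = A_rel0, B_rel0 = B_rel0,
              S_e = S_e, F_e = F_e,
              fv_act_dependence = isTRUE(fv_act_dependence)),
    PEE = list(L_PEE0 = L_PEE0, nu_PEE = nu_PEE, F_PEE = F_PEE),
    SEE = list(l_SEE0 = l_SEE0, dU_SEE_nll = dU_SEE_nll,
               dU_SEE_l = dU_SEE_l, dF_SEE0 = dF_SEE0),
    SDE = list(D_SE = D_SE, R_SE = R_SE),
    ACT = list(tau_act = tau_act, a_min = a_min)
  )
  class(p) <- "mtu_parameters"
  validate_mtu_parameters(p)
  # derived constants
  p$PEE$K_PEE <- F_PEE * F_max /
    (l_opt * (dW_des + 1 - L_PEE0))^nu_PEE
  p$SEE$nu_SEE <- dU_SEE_nll / dU_SEE_l
  p$SEE$K_SEE_nl <- dF_SEE0 / (dU_SEE_nll * l_SEE0)^p$SEE$nu_SEE
  p$SEE$K_SEE_l <- dF_SEE0 / (dU_SEE_l * l_SEE0)
  p$SDE$d_SE_max <- D_SE * F_max * A_rel0 / (l_opt * B_rel0)
  p
}

validate_mtu_parameters <- function(p) {
  ce <- p$CE
  stopifnot(
    ce$F_max > 0, ce$l_opt > 0,
    ce$dW_asc > 0, ce$dW_des > 0,
    ce$nu_asc >= 1, ce$nu_des >= 1,
    ce$A_rel0 > 0, ce$B_rel0 > 0,
    ce$S_e > 1, ce$F_e > 1,
    p$PEE$L_PEE0 > 0, p$PEE$nu_PEE >= 1, p$PEE$F_PEE >= 0,
    p$SEE$l_SEE0 > 0, p$SEE$dU_SEE_nll > 0,
    p$SEE$dU_SEE_l > 0, p$SEE$dF_SEE0 > 0,
    p$SDE$D_SE >= 0, p$SDE$R_SE >= 0, p$SDE$R_SE <= 1,
    p$ACT$tau_act > 0,
    p$ACT$a_min >= 0, p$ACT$a_min < 1
  )
  invisible(p)
}

#' Hopper parameters
#'
#' Parameters of the two-segment, single-leg vertical hopper driven by the MTU
#' as a knee extensor. The leg has two massless segments of equal length
#' joined by a knee hinge; the body is a point mass at the hip. The MTU length
#' is an affine function of the knee angle with constant moment arm:
#' `l_MTU = l_MTU_ref + r * (phi_ref - phi)` (the extensor shortens as the
#' knee extends). During flight the knee is locked at `phi_flight`.
#'
#' The default `l_MTU_ref` is chosen so that the internal CE/SEE equilibrium
#' during flight (activity at its stationary value for the flight stimulation
#' `u0`) sits at a normalized CE length of 0.56; see
#' [flight_equilibrium_l_mtu()] which recomputes that value from any MTU
#' parameter set.
#'
#' @param m body mass \[kg\].
#' @param l_seg segment length \[m\] (two equal segments).
#' @param r knee extension moment arm \[m\].
#' @param phi_ref reference knee angle \[rad\] at which `l_MTU = l_MTU_ref`.
#' @param phi_flight knee angle during flight \[rad\] (knee locked).
#' @param l_MTU_ref MTU length at the reference knee angle \[m\]. The default
#'   `NULL` resolves to [flight_equilibrium_l_mtu()] with `lce_norm_td`.
#' @param lce_norm_td normalized CE length that the flight equilibrium should
#'   produce when `l_MTU_ref` is derived (default 0.56).
#' @param g gravitational acceleration \[m/s^2\].
#' @param u0 flight/preflex stimulation level (default 0.15).
#' @param b stimulation ramp slope after the preflex phase \[1/s\]
#'   (default 10).
#' @param t_px preflex duration \[s\] (default 0.030).
#' @param dh perturbation step height \[m\] (default 0.05; step-up raises the
#'   ground by `dh`, step-down lowers it).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param apex_tol apex-height convergence tolerance of the limit-cycle search
#'   \[m\].
#' @param mtu MTU parameter set, see [mtu_parameters()].
#'
#' @return an object of class `hopper_parameters` (named list; the MTU set is
#'   its `mtu` component).
#' @export
hopper_parameters <- function(m = 80, l_seg = 0.50, r = 0.07,
                              phi_ref = 2.0, phi_flight = phi_ref,
                              l_MTU_ref = NULL, lce_norm_td = 0.56,
                              g = 9.81,
                              u0 = 0.15, b = 10, t_px = 0.030,
                              dh = 0.05,
                              rtol = 1e-8, atol = 1e-10,
                              apex_tol = 1e-4,
                              mtu = mtu_parameters()) {
  stopifnot(m > 0, l_seg > 0, r > 0,
            phi_ref > 0, phi_ref < pi,
            phi_flight > 0, phi_flight < pi,
            u0 > 0, u0 <= 1, b >= 0, t_px > 0, dh >= 0,
            inherits(mtu, "mtu_parameters"))
  if (is.null(l_MTU_ref)) {
    l_MTU_ref <- flight_equilibrium_l_mtu(mtu, u0 = u0,
                                          lce_norm = lce_norm_td)
  }
  stopifnot(l_MTU_ref > 0)
  p <- list(m = m, l_seg = l_seg, r = r,
            phi_ref = phi_ref, phi_flight = phi_flight,
            l_MTU_ref = l_MTU_ref, g = g,
            u0 = u0, b = b, t_px = t_px, dh = dh,
            rtol = rtol, atol = atol, apex_tol = apex_tol,
            mtu = mtu)
  class(p) <- "hopper_parameters"
  p
}

#' MTU length that places the flight CE equilibrium at a target length
#'
#' With the knee locked, the CE settles where the contractile side
#' (CE + PEE at zero velocity) balances the SEE. This helper inverts that
#' balance: given a target normalized CE length and the stationary activity of
#' the flight stimulation, it returns the (fixed) MTU length for which the
#' equilibrium sits exactly at the target.
#'
#' @param mtu MTU parameters.
#' @param u0 flight stimulation level.
#' @param lce_norm target normalized CE length at equilibrium.
#' @return MTU length \[m\].
#' @export
flight_equilibrium_l_mtu <- function(mtu, u0 = 0.15, lce_norm = 0.56) {
  a <- activation_stationary(u0, mtu)
  f <- ce_force(lce_norm, 0, a, mtu) + parallel_elastic_force(lce_norm, mtu)
  lce_norm * mtu$CE$l_opt + serial_elastic_inverse(f, mtu)
}

# SEE length (m) carrying a given force (N); inverse of the SEE force law.
serial_elastic_inverse <- function(f, params) {
  s <- params$SEE
  stopifnot(f >= 0)
  if (f <= 0) return(s$l_SEE0)
  if (f <= s$dF_SEE0) {
    dl <- (f / s$K_SEE_nl)^(1 / s$nu_SEE)
  } else {
    dl <- s$dU_SEE_nll * s$l_SEE0 + (f - s$dF_SEE0) / s$K_SEE_l
  }
  s$l_SEE0 + dl
}

#' Read / write a parameter configuration file
#'
#' Flat YAML with one section per element (`CE`, `PEE`, `SEE`, `SDE`, `ACT`)
#' and an optional `HOPPER` section; SI units. The file is schema-validated on
#' load: unknown keys raise an error, missing keys fall back to defaults.
#'
#' @param path file path.
#' @param params for `write_mtu_config`, an `mtu_parameters` or
#'   `hopper_parameters` object.
#' @return `read_mtu_config` returns an `mtu_parameters` object (or
#'   `hopper_parameters` if the file has a `HOPPER` section).
#' @export
read_mtu_config <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("CE", "PEE", "SEE", "SDE", "ACT", "HOPPER")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  args <- list()
  sec_args <- function(sec, allowed) {
    x <- raw[[sec]]
    if (is.null(x)) return(list())
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    }
    x
  }
  args <- c(args,
    sec_args("CE", c("F_max", "l_opt", "dW_asc", "nu_asc", "dW_des", "nu_des",
                     "A_rel0", "B_rel0", "S_e", "F_e", "fv_act_dependence")),
    sec_args("PEE", c("L_PEE0", "nu_PEE", "F_PEE")),
    sec_args("SEE", c("l_SEE0", "dU_SEE_nll", "dU_SEE_l", "dF_SEE0")),
    sec_args("SDE", c("D_SE", "R_SE")),
    sec_args("ACT", c("tau_act", "a_min")))
  mtu <- do.call(mtu_parameters, args)
  hop <- sec_args("HOPPER", c("m", "l_seg", "r", "phi_ref", "phi_flight",
                              "l_MTU_ref", "lce_norm_td", "g", "u0", "b",
                              "t_px", "dh", "rtol", "atol", "apex_tol"))
  if (length(raw$HOPPER)) {
    do.call(hopper_parameters, c(hop, list(mtu = mtu)))
  } else {
    mtu
  }
}

#' @rdname read_mtu_config
#' @export
write_mtu_config <- function(params, path) {
  if (inherits(params, "hopper_parameters")) {
    hop <- params[setdiff(names(params), "mtu")]
    mtu <- params$mtu
  } else {
    hop <- NULL
    mtu <- params
  }
  stopifnot(inherits(mtu, "mtu_parameters"))
  drop_derived <- function(x, keep) x[intersect(keep, names(x))]
  out <- list(
    CE = mtu$CE,
    PEE = drop_derived(mtu$PEE, c("L_PEE0", "nu_PEE", "F_PEE")),
    SEE = drop_derived(mtu$SEE, c("l_SEE0", "dU_SEE_nll", "dU_SEE_l", "dF_SEE0")),
    SDE = drop_derived(mtu$SDE, c("D_SE", "R_SE")),
    ACT = mtu$ACT
  )
  if (!is.null(hop)) out$HOPPER <- hop
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
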