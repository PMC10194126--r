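#' Synthetic skinned-fiber generator parameters
#'
#' Population-level parameters of the synthetic fiber generator. The
#' generator is deliberately *not* the Hill model: it is a piecewise
#' elastic + saturating-viscous construction that reproduces the
#' phenomenology reported for skinned fibers under these boundary conditions
#' (short-range stiffness with weak velocity dependence inside the tested
#' band but a clear dynamic-vs-quasistatic difference, a velocity-ordered
#' "give" after the short-range-stiffness region, activity scaling of all
#' gains, slow degradation over a session, and measurement noise). All shape
#' parameters are inventions chosen for that phenomenology and are
#' configurable.
#'
#' The noiseless generator force (in units of the fiber's current maximal
#' force) at normalized length `l`, normalized velocity `v` and activity `a`
#' is
#' \deqn{F = a F_{isom}(l) + \kappa a \phi(v_{pk}) \min(s, \delta_{srs})
#'       + k_{post} a (s - \delta_{srs})_+ + c_0 a \frac{v}{v_{c} + v}
#'         1[s > \delta_{srs}]}
#' with `s = (l - l_on)+` the stretch past the force onset length and
#' `phi(v_pk) = 1 + beta * v_pk^h / (v_sat^h + v_pk^h)` a trial-level
#' velocity factor evaluated at the trial's peak stretch velocity. The
#' sigmoidal exponent `h` (default 2) makes the short-range stiffness flat
#' both across the 3 to 5 l_opt/s dynamic band and across the quasistatic
#' speeds, while keeping the dynamic level clearly above the quasistatic
#' one — the velocity dependence lives between the two speed regimes, as
#' reported for stretches spanning orders of magnitude in speed.
#'
#' @param F_max_mN,l_opt_mm population means of the per-fiber maximal force
#'   \[mN\] and optimal length \[mm\].
#' @param cv_fiber log-normal coefficient of variation of the per-fiber
#'   `F_max`, `l_opt` and gains (fiber heterogeneity).
#' @param kappa short-range-stiffness gain \[F_max / l_opt per unit
#'   activity\].
#' @param beta,v_sat,h_sat velocity factor shape: `1 + beta * v_pk^h_sat /
#'   (v_sat^h_sat + v_pk^h_sat)` with `v_pk` the trial's peak stretch
#'   velocity \[l_opt/s\].
#' @param delta_srs extent of the short-range-stiffness region \[l_opt\]
#'   (default 0.02, i.e. the 0.57 to 0.59 window).
#' @param l_on normalized length at force onset (default 0.57).
#' @param k_post post-SRS length gain \[F_max / l_opt per unit activity\].
#' @param c_post,v_sat_post post-SRS viscous gain \[F_max per unit activity\]
#'   and its saturation speed \[l_opt/s\].
#' @param rho degradation factor per activation (geometric).
#' @param sigma white measurement noise SD \[F_max\].
#' @param sigma_base per-trial baseline offset SD \[F_max\] (slow drift of
#'   the force transducer baseline between activations).
#' @param cv_trial per-trial multiplicative gain jitter (log-normal CV).
#' @param fs_dynamic,fs_quasistatic sampling rates \[Hz\].
#' @param isom_params an [mtu_parameters()] set used only for the
#'   `F_isom(l)` base shape of the generator (the force-length relation is
#'   shared biology, not Hill-model dynamics).
#' @return an object of class `fiber_population`.
#' @export
fiber_population <- function(F_max_mN = 0.8, l_opt_mm = 1.0,
                             cv_fiber = 0.15,
                             kappa = 20, beta = 1.0, v_sat = 0.4, h_sat = 2,
                             delta_srs = 0.02, l_on = 0.57,
                             k_post = 6, c_post = 0.12, v_sat_post = 1.0,
                             rho = 0.995,
                             sigma = 0.01, sigma_base = 0.043,
                             cv_trial = 0.03,
                             fs_dynamic = 1e4, fs_quasistatic = 1e3,
                             isom_params = mtu_parameters()) {
  p <- list(F_max_mN = F_max_mN, l_opt_mm = l_opt_mm, cv_fiber = cv_fiber,
            kappa = kappa, beta = beta, v_sat = v_sat, h_sat = h_sat,
            delta_srs = delta_srs, l_on = l_on,
            k_post = k_post, c_post = c_post, v_sat_post = v_sat_post,
            rho = rho, sigma = sigma, sigma_base = sigma_base,
            cv_trial = cv_trial,
            fs_dynamic = fs_dynamic, fs_quasistatic = fs_quasistatic,
            isom_params = isom_params)
  stopifnot(p$kappa >= 0, p$k_post >= 0, p$c_post >= 0,
            p$rho > 0.9, p$rho <= 1, p$sigma >= 0, p$sigma_base >= 0)
  class(p) <- "fiber_population"
  p
}

#' Sample individual fibers from the population
#'
#' Per-fiber `F_max`, `l_opt` and the three gains are drawn from log-normal
#' distributions around the population values (CV `cv_fiber`).
#'
#' @param pop [fiber_population()] object.
#' @param n number of fibers (default 9).
#' @return list of per-fiber parameter lists (class `fiber_parameters`),
#'   each with a `fiber_id`.
#' @keywords internal
sample_fibers <- function(pop, n = 9) {
  sdl <- sqrt(log(1 + pop$cv_fiber^2))
  draw <- function(mu) mu * exp(stats::rnorm(n, -sdl^2 / 2, sdl))
  F_max <- draw(pop$F_max_mN); l_opt <- draw(pop$l_opt_mm)
  kap <- draw(pop$kappa); kp <- draw(pop$k_post); cp <- draw(pop$c_post)
  lapply(seq_len(n), function(i) {
    f <- list(fiber_id = i, F_max_mN = F_max[i], l_opt_mm = l_opt[i],
              kappa = kap[i], k_post = kp[i], c_post = cp[i], pop = pop)
    class(f) <- "fiber_parameters"
    f
  })
}

# Noiseless generator force in units of the fiber's (degraded) maximal force.
fiber_force_closed_form <- function(lce_norm, vce_norm, a, fiber,
                                    v_pk = max(vce_norm)) {
  pop <- fiber$pop
  s <- pmax(lce_norm - pop$l_on, 0)
  phi_v <- 1 + pop$beta * v_pk^pop$h_sat /
    (pop$v_sat^pop$h_sat + v_pk^pop$h_sat)
  srs <- fiber$kappa * a * phi_v * pmin(s, pop$delta_srs)
  post_len <- fiber$k_post * a * pmax(s - pop$delta_srs, 0)
  post_vis <- fiber$c_post * a *
    (pmax(vce_norm, 0) / (pop$v_sat_post + pmax(vce_norm, 0))) *
    (s > pop$delta_srs)
  base <- a * isom_force_length(lce_norm, pop$isom_params)
  pmax(base + srs + post_len + post_vis, 0)
}

#' Synthetic fiber force response to a prescribed stretch
#'
#' Evaluates the generator (see [fiber_population()]) along a CE kinematic
#' trajectory at a constant activity, applies the session degradation factor,
#' a per-trial gain jitter and baseline offset, and white measurement noise.
#' Deterministic for a given `rng_seed`.
#'
#' @param traj a [ce_trajectory()].
#' @param a constant activity in (0, 1\].
#' @param fiber a per-fiber parameter list from `sample_fibers()`.
#' @param rng_seed integer seed for the trial's noise draws.
#' @param n_activations number of activations the fiber has already
#'   undergone (sets the degradation factor `rho^n_activations`).
#' @return a `fiber_trial` object: list with `data` (data.frame `t_s`,
#'   `length_mm`, `velocity_mm_s`, `force_mN`), `fiber_id`, `kind`
#'   (`"perturbation"`), condition labels, `activity`, `rng_seed`,
#'   `degradation`.
#' @export
fiber_force_response <- function(traj, a, fiber, rng_seed,
                                 n_activations = 0) {
  stopifnot(inherits(traj, "ce_trajectory"), a > 0, a <= 1)
  pop <- fiber$pop
  f_norm <- fiber_force_closed_form(traj$lce_norm, traj$vce_norm_per_s, a,
                                    fiber)
  noise <- with_trial_rng(rng_seed, {
    gain <- if (pop$cv_trial > 0) {
      sdl <- sqrt(log(1 + pop$cv_trial^2))
      exp(stats::rnorm(1, -sdl^2 / 2, sdl))
    } else 1
    base_off <- stats::rnorm(1, 0, pop$sigma_base)
    white <- stats::rnorm(length(f_norm), 0, pop$sigma)
    list(gain = gain, base_off = base_off, white = white)
  })
  deg <- pop$rho^n_activations
  f_norm <- pmax(f_norm * noise$gain + noise$base_off + noise$white, 0)
  force_mN <- deg * fiber$F_max_mN * f_norm
  trial <- list(
    data = data.frame(t_s = traj$t_s,
                      length_mm = traj$lce_norm * fiber$l_opt_mm,
                      velocity_mm_s = traj$vce_norm_per_s * fiber$l_opt_mm,
                      force_mN = force_mN),
    fiber_id = fiber$fiber_id,
    kind = "perturbation",
    scenario = attr(traj, "scenario"),
    speed_condition = attr(traj, "speed_condition"),
    activity = a,
    rng_seed = rng_seed,
    degradation = deg,
    fiber = fiber)
  class(trial) <- "fiber_trial"
  trial
}

#' Isometric reference contraction
#'
#' Reference trial at optimal length and full activity: the force rises
#' exponentially to the fiber's current (degraded) maximal force and holds a
#' plateau defined, as in the rig protocol, by a force rise of less than 1%
#' within the final 1.5 s.
#'
#' @inheritParams fiber_force_response
#' @param duration trial duration \[s\] (default 3).
#' @param tau_rise force rise time constant \[s\].
#' @return a `fiber_trial` with `kind = "isometric_reference"` and a
#'   `plateau_mN` element (noise-free plateau value).
#' @export
isometric_reference_trial <- function(fiber, rng_seed, n_activations = 0,
                                      duration = 3, tau_rise = 0.3) {
  pop <- fiber$pop
  t_s <- seq(0, duration, by = 1 / pop$fs_quasistatic)
  deg <- pop$rho^n_activations
  plateau <- deg * fiber$F_max_mN
  f <- plateau * (1 - exp(-t_s / tau_rise))
  white <- with_trial_rng(rng_seed,
                          stats::rnorm(length(f), 0, pop$sigma))
  force <- pmax(f + white * deg * fiber$F_max_mN, 0)
  trial <- list(
    data = data.frame(t_s = t_s,
                      length_mm = rep(fiber$l_opt_mm, length(t_s)),
                      velocity_mm_s = rep(0, length(t_s)),
                      force_mN = force),
    fiber_id = fiber$fiber_id,
    kind = "isometric_reference",
    scenario = NA_character_, speed_condition = NA_character_,
    activity = 1,
    rng_seed = rng_seed,
    degradation = deg,
    plateau_mN = plateau,
    fiber = fiber)
  class(trial) <- "fiber_trial"
  trial
}

# run an expression under a temporary RNG state seeded with `seed`
with_trial_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a full synthetic fiber experiment session
#'
#' Emulates the in vitro protocol: `n_fibers` fibers, and for each fiber one
#' block per perturbation x speed condition containing the three activity
#' levels in randomized order, with the block order itself randomized and
#' every block bracketed by isometric reference contractions at optimal
#' length and full activity (consecutive blocks share the reference between
#' them). Every activation (perturbation trial or reference) advances the
#' fiber's degradation state by one step. Fully reproducible from `seed`.
#'
#' @param trajectories named list of [ce_trajectory()] objects, one per
#'   condition, with names `"<scenario>.<speed>"` (e.g. `"down.dynamic"`),
#'   as produced by [pipeline_trajectories()].
#' @param n_fibers number of fibers (default 9).
#' @param activities activity levels (default `c(0.05, 0.15, 0.25)`).
#' @param seed integer master seed.
#' @param pop [fiber_population()] object.
#' @return an object of class `fiber_session`: list with `trials` (list of
#'   `fiber_trial`), `manifest` (data.frame: fiber, trial index, kind,
#'   scenario, speed_condition, activity, block, seed), `fibers`, `pop`,
#'   `seed`.
#' @export
generate_experiment <- function(trajectories,
                                n_fibers = 9,
                                activities = c(0.05, 0.15, 0.25),
                                seed = 1,
                                pop = fiber_population()) {
  stopifnot(length(trajectories) >= 1, length(activities) >= 1)
  conds <- names(trajectories)
  if (is.null(conds) || any(!nzchar(conds))) {
    stop("`trajectories` must be a named list ('<scenario>.<speed>')")
  }
  trials <- list(); manifest <- list()
  fibers <- with_trial_rng(seed, sample_fibers(pop, n_fibers))
  # per-fiber block/activity orders and per-trial seeds, all from the master
  plan <- with_trial_rng(seed + 1, {
    lapply(seq_len(n_fibers), function(i) {
      blocks <- sample(conds)
      acts <- lapply(blocks, function(b) sample(activities))
      list(blocks = blocks, acts = acts,
           seeds = sample.int(2^30, length(blocks) * (length(activities) + 1) + 1))
    })
  })
  idx <- 0
  for (i in seq_len(n_fibers)) {
    fiber <- fibers[[i]]
    pl <- plan[[i]]
    n_act <- 0          # activations so far for this fiber
    s_ix <- 0
    take_seed <- function() {
      s_ix <<- s_ix + 1
      pl$seeds[s_ix]
    }
    add <- function(trial, block) {
      idx <<- idx + 1
      trials[[idx]] <<- trial
      manifest[[idx]] <<- data.frame(
        fiber = i, trial_index = idx, kind = trial$kind,
        scenario = trial$scenario, speed_condition = trial$speed_condition,
        activity = trial$activity, block = block, seed = trial$rng_seed)
    }
    # leading reference
    add(isometric_reference_trial(fiber, take_seed(), n_act), block = 0L)
    n_act <- n_act + 1
    for (b in seq_along(pl$blocks)) {
      cond <- pl$blocks[b]
      traj <- trajectories[[cond]]
      for (a in pl$acts[[b]]) {
        add(fiber_force_response(traj, a, fiber, take_seed(), n_act),
            block = b)
        n_act <- n_act + 1
      }
      # closing reference (doubles as the next block's opening reference)
      add(isometric_reference_trial(fiber, take_seed(), n_act), block = b)
      n_act <- n_act + 1
    }
  }
  session <- list(trials = trials, manifest = do.call(rbind, manifest),
                  fibers = fibers, pop = pop, seed = seed)
  class(session) <- "fiber_session"
  session
}

#' Write a fiber session to disk
#'
#' One CSV per trial (`t_s, length_mm, velocity_mm_s, force_mN`) plus a
#' session manifest CSV, mirroring a fiber-rig export.
#'
#' @param session a `fiber_session`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_fiber_session <- function(session, dir) {
  stopifnot(inherits(session, "fiber_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- session$manifest
  man$file <- sprintf("trial_%04d.csv", man$trial_index)
  for (k in seq_along(session$trials)) {
    utils::write.csv(session$trials[[k]]$data,
                     file.path(dir, man$file[k]), row.names = FALSE)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
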