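noiseless_pop <- fiber_population(sigma = 0, sigma_base = 0,
                                  cv_trial = 0, cv_fiber = 0)
one_fiber <- function(pop = noiseless_pop) {
  preflexr:::with_trial_rng(1, preflexr:::sample_fibers(pop, 1))[[1]]
}

test_that("noiseless trials equal the closed-form generator exactly", {
  fib <- one_fiber()
  traj <- ramp_trajectory(v_norm = 4, duration = 0.03)
  tr <- fiber_force_response(traj, 0.15, fib, rng_seed = 99)
  expected <- preflexr:::fiber_force_closed_form(
    traj$lce_norm, traj$vce_norm_per_s, 0.15, fib) * fib$F_max_mN
  expect_equal(tr$data$force_mN, expected, tolerance = 1e-12)
  # deterministic given the seed even with noise on
  noisy <- fiber_population()
  fib2 <- one_fiber(noisy)
  t1 <- fiber_force_response(traj, 0.15, fib2, rng_seed = 5)
  t2 <- fiber_force_response(traj, 0.15, fib2, rng_seed = 5)
  expect_identical(t1$data, t2$data)
})

test_that("SRS slope scales linearly with activity (ratio 5 between 25% and 5%)", {
  fib <- one_fiber()
  traj <- ramp_trajectory(v_norm = 4, duration = 0.03)
  slope_of <- function(a) {
    tr <- fiber_force_response(traj, a, fib, 1)
    d <- data.frame(lce_norm = tr$data$length_mm / fib$l_opt_mm,
                    f_norm = tr$data$force_mN / fib$F_max_mN)
    srs_stiffness(d)
  }
  # remove the common isometric base slope before taking the ratio
  base_slope <- function(a) {
    l <- seq(0.57, 0.59, by = 1e-4)
    stats::cov(l, a * isom_force_length(l, noiseless_pop$isom_params)) /
      stats::var(l)
  }
  r <- (slope_of(0.25) - base_slope(0.25)) /
    (slope_of(0.05) - base_slope(0.05))
  expect_equal(r, 5, tolerance = 1e-6)
})

test_that("SRS is flat across the dynamic band, post-SRS force ordered by speed", {
  fib <- one_fiber()
  t3 <- ramp_trajectory(v_norm = 3, duration = 0.03)
  t5 <- ramp_trajectory(v_norm = 5, duration = 0.018)
  s <- lapply(list(t3, t5), function(tr) {
    d <- fiber_force_response(tr, 0.15, fib, 1)$data
    nd <- data.frame(lce_norm = d$length_mm / fib$l_opt_mm,
                     f_norm = d$force_mN / fib$F_max_mN)
    list(srs = srs_stiffness(nd), nd = nd)
  })
  expect_lt(abs(s[[1]]$srs - s[[2]]$srs) / s[[1]]$srs, 0.10)
  # at matched lengths past the SRS region the faster stretch carries more force
  grid <- seq(0.595, 0.61, by = 1e-3)
  f3 <- stats::approx(s[[1]]$nd$lce_norm, s[[1]]$nd$f_norm, grid)$y
  f5 <- stats::approx(s[[2]]$nd$lce_norm, s[[2]]$nd$f_norm, grid)$y
  expect_true(all(f5 > f3))
})

test_that("a session has the full factorial design with bracketing references", {
  sess <- px_session()
  man <- sess$manifest
  pert <- man[man$kind == "perturbation", ]
  expect_equal(nrow(pert), 9 * 3 * 3 * 2)
  expect_equal(nrow(man[man$kind == "isometric_reference", ]), 9 * 7)
  # every block of every fiber is bracketed by references
  for (f in unique(man$fiber)) {
    sub <- man[man$fiber == f, ]
    refs <- sub$trial_index[sub$kind == "isometric_reference"]
    for (b in unique(sub$block[sub$kind == "perturbation"])) {
      ix <- sub$trial_index[sub$kind == "perturbation" & sub$block == b]
      expect_true(any(refs < min(ix)) && any(refs > max(ix)))
    }
  }
  # reproducibility: same seed gives an identical manifest
  sess2 <- generate_experiment(px_trajectories(), seed = 7)
  expect_identical(sess$manifest, sess2$manifest)
  sess3 <- generate_experiment(px_trajectories(), seed = 8)
  expect_false(identical(sess3$manifest$seed, sess$manifest$seed))
})

test_that("reference contractions decay geometrically and satisfy the plateau criterion", {
  fib <- one_fiber()
  r0 <- isometric_reference_trial(fib, 1, n_activations = 0)
  expect_equal(r0$plateau_mN, fib$F_max_mN)
  rk <- isometric_reference_trial(fib, 1, n_activations = 6)
  expect_equal(rk$plateau_mN, noiseless_pop$rho^6 * fib$F_max_mN)
  # plateau criterion: force rise within the final 1.5 s below 1%
  d <- r0$data
  t_end <- max(d$t_s)
  rise <- d$force_mN[d$t_s == t_end] -
    d$force_mN[which.min(abs(d$t_s - (t_end - 1.5)))]
  expect_lt(rise / r0$plateau_mN, 0.01)
  # reference plateaus decay monotonically through a noiseless session
  sess <- generate_experiment(px_trajectories()[c("none.dynamic")],
                              n_fibers = 1, seed = 3, pop = noiseless_pop)
  refs <- which(sess$manifest$kind == "isometric_reference")
  plateaus <- vapply(refs, function(k) sess$trials[[k]]$plateau_mN, 0)
  expect_true(all(diff(plateaus) < 0))
})
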