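test_that("normalization interpolates the bracketing reference plateaus", {
  pop <- fiber_population(sigma = 0, sigma_base = 0, cv_trial = 0,
                          cv_fiber = 0, rho = 0.98)
  sess <- generate_experiment(px_trajectories()["none.dynamic"],
                              n_fibers = 1, activities = c(0.05, 0.15, 0.25),
                              seed = 2, pop = pop)
  man <- sess$manifest
  pert_ix <- man$trial_index[man$kind == "perturbation"]
  # middle trial of a 3-trial block sits midway between the references
  mid <- pert_ix[2]
  nt <- normalize_trial(sess$trials[[mid]], sess)
  ref_pre <- sess$trials[[1]]$plateau_mN
  ref_post <- sess$trials[[5]]$plateau_mN
  # plateau estimated from the trace tail: agreement to the estimator bias
  expect_equal(attr(nt, "divisor_mN"), (ref_pre + ref_post) / 2,
               tolerance = 1e-3)
  # normalized force of a noiseless trial recovers the generator closed form
  # up to the (small) degradation-interpolation mismatch
  tr <- sess$trials[[mid]]
  expected <- preflexr:::fiber_force_closed_form(
    tr$data$length_mm / tr$fiber$l_opt_mm,
    tr$data$velocity_mm_s / tr$fiber$l_opt_mm,
    tr$activity, tr$fiber)
  expect_equal(nt$f_norm, expected, tolerance = 0.01)
  # no degradation -> divisor is exactly the fiber's F_max
  pop1 <- fiber_population(sigma = 0, sigma_base = 0, cv_trial = 0,
                           cv_fiber = 0, rho = 1)
  sess1 <- generate_experiment(px_trajectories()["none.dynamic"],
                               n_fibers = 1, seed = 2, pop = pop1)
  nt1 <- normalize_trial(sess1$trials[[2]], sess1)
  expect_equal(attr(nt1, "divisor_mN"), sess1$fibers[[1]]$F_max_mN,
               tolerance = 1e-3)
  expect_error(normalize_trial(sess$trials[[1]], sess), "perturbation")
})

test_that("analysis windows follow the 30 ms / matched-length rule", {
  seg <- data.frame(t_s = seq(0, 0.1, by = 1e-3),
                    lce_norm = 0.56 + 4 * seq(0, 0.1, by = 1e-3),
                    f_norm = 0.1)
  attr(seg, "speed_condition") <- "dynamic"
  w <- preflex_window(seg)
  expect_equal(max(w$t_s), 0.030, tolerance = 1e-9)
  # quasistatic: window ends exactly at the matched length (interpolated)
  seg$t_s <- seg$t_s * 80
  attr(seg, "speed_condition") <- "quasistatic"
  wq <- preflex_window(seg, matched_end_length = 0.6123)
  expect_equal(wq$lce_norm[nrow(wq)], 0.6123, tolerance = 1e-12)
  expect_error(preflex_window(seg, matched_end_length = 0.5),
               "not above the start")
  expect_error(preflex_window(seg, matched_end_length = 2), "never reaches")
  attr(seg, "speed_condition") <- "quasistatic"
  expect_error(preflex_window(seg), "matched_end_length")
})

test_that("trapezoidal work matches closed forms", {
  # linear ramp 0 -> 1 over 0.02: triangle area
  l <- seq(0.57, 0.59, length.out = 50)
  seg <- data.frame(lce_norm = l, f_norm = seq(0, 1, length.out = 50))
  expect_equal(mechanical_work(seg), 0.01, tolerance = 1e-12)
  # constant force
  seg2 <- data.frame(lce_norm = l, f_norm = rep(0.3, 50))
  expect_equal(mechanical_work(seg2), 0.3 * 0.02, tolerance = 1e-12)
  # random piecewise-linear profile against the knot-wise closed form
  set.seed(9)
  for (i in 1:10) {
    lk <- sort(runif(8, 0.5, 0.8))
    fk <- runif(8, 0, 1)
    seg3 <- data.frame(lce_norm = lk, f_norm = fk)
    expect_equal(mechanical_work(seg3), piecewise_linear_work(lk, fk),
                 tolerance = 1e-12)
  }
  expect_error(mechanical_work(data.frame(lce_norm = 1, f_norm = 1)))
})

test_that("work is invariant under time reparameterization of the same force-length path", {
  set.seed(3)
  t <- seq(0, 0.03, by = 1e-4)
  l <- 0.56 + cumsum(runif(length(t), 0, 4e-4))
  f <- 0.05 + 10 * (l - 0.56) + rnorm(length(t), 0, 0.002)
  w_dyn <- mechanical_work(data.frame(lce_norm = l, f_norm = f))
  w_qs <- mechanical_work(data.frame(lce_norm = l, f_norm = f,
                                     t_s = t * 80))
  expect_identical(w_dyn, w_qs)
})

test_that("short-range stiffness is the OLS slope in the 0.57-0.59 window", {
  l <- seq(0.56, 0.63, by = 5e-4)
  seg <- data.frame(lce_norm = l, f_norm = 2 + 12 * (l - 0.57))
  expect_equal(srs_stiffness(seg), 12, tolerance = 1e-9)
  seg$f_norm <- 0.4
  expect_equal(srs_stiffness(seg), 0)
  expect_error(srs_stiffness(seg[seg$lce_norm < 0.571, ]), "fewer than 3")
  # noiseless quasistatic synthetic fiber recovers the generator SRS gain
  pop <- fiber_population(sigma = 0, sigma_base = 0, cv_trial = 0,
                          cv_fiber = 0)
  fib <- preflexr:::with_trial_rng(1, preflexr:::sample_fibers(pop, 1))[[1]]
  qs <- make_quasistatic(ramp_trajectory(v_norm = 4, duration = 0.03), 80)
  d <- fiber_force_response(qs, 0.15, fib, 1)$data
  nd <- data.frame(lce_norm = d$length_mm / fib$l_opt_mm,
                   f_norm = d$force_mN / fib$F_max_mN)
  v_pk <- max(qs$vce_norm_per_s)
  gain <- fib$kappa * 0.15 *
    (1 + pop$beta * v_pk^pop$h_sat / (pop$v_sat^pop$h_sat + v_pk^pop$h_sat))
  measured <- srs_stiffness(nd)
  base <- stats::cov(nd$lce_norm, 0.15 * isom_force_length(nd$lce_norm, pop$isom_params)) /
    stats::var(nd$lce_norm)  # slope share of the isometric base
  expect_equal(measured - base, gain, tolerance = 0.01 * gain)
})

test_that("post-SRS work equals the matched sub-segment work", {
  l <- seq(0.57, 0.66, by = 1e-3)
  f <- 0.1 + 3 * (l - 0.57)
  seg <- data.frame(lce_norm = l, f_norm = f)
  expect_equal(post_srs_work(seg, common_end_length = 0.59), 0)
  # linear force: trapezoid closed form on [0.59, 0.64]
  f59 <- 0.1 + 3 * 0.02; f64 <- 0.1 + 3 * 0.07
  expect_equal(post_srs_work(seg, 0.64), (f59 + f64) / 2 * 0.05,
               tolerance = 1e-12)
  # equals mechanical_work on the clipped sub-segment
  sub <- seg[seg$lce_norm >= 0.59 & seg$lce_norm <= 0.64, ]
  expect_equal(post_srs_work(seg, 0.64), mechanical_work(sub),
               tolerance = 1e-9)
  expect_error(post_srs_work(seg, 0.58), "before the end")
  expect_error(post_srs_work(seg, 0.9), "does not reach")
})

test_that("work difference is plain arithmetic with condition checking", {
  expect_equal(work_difference(0.012, 0.010), 0.002)
  expect_equal(work_difference(0.01, 0.01), 0)
  expect_equal(work_difference(0.010, 0.012), -work_difference(0.012, 0.010))
  chk <- list(dynamic = list(fiber_id = 1, scenario = "up", activity = 0.15),
              quasistatic = list(fiber_id = 1, scenario = "down", activity = 0.15))
  expect_error(work_difference(1, 2, check = chk), "mismatch")
})

test_that("session analysis produces a complete metrics table with sane values", {
  an <- px_analysis()
  m <- an$metrics
  expect_equal(nrow(m), 162)
  expect_true(all(table(m$scenario, m$speed_condition, m$activity) == 9))
  expect_true(all(m$work > 0))
  expect_true(all(is.finite(m$srs)))
  expect_true(all(is.na(m$post_srs[m$speed_condition == "quasistatic"])))
  expect_true(all(m$post_srs[m$speed_condition == "dynamic"] >= 0))
  expect_equal(nrow(an$work_diff), 81)
  # matched windows: quasistatic window end equals the dynamic end length
  dyn <- m[m$speed_condition == "dynamic", ]
  qs <- m[m$speed_condition == "quasistatic", ]
  mrg <- merge(dyn, qs, by = c("fiber", "scenario", "activity"))
  expect_equal(mrg$window_end_length.x, mrg$window_end_length.y,
               tolerance = 1e-6)
})
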