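mtu <- mtu_parameters()
mtu_const <- mtu_parameters(fv_act_dependence = FALSE)

test_that("isometric force-length bell curve has the right peak, tails and widths", {
  expect_equal(isom_force_length(1, mtu), 1)
  # tails decay toward zero on both limbs
  expect_lt(isom_force_length(0.05, mtu), 0.05)
  expect_lt(isom_force_length(3, mtu), 1e-6)
  l_tail <- c(0.8, 0.5, 0.2, 0.05)
  expect_true(all(diff(isom_force_length(l_tail, mtu)) < 0))
  # one width below/above the optimum the curve is at exp(-1)
  expect_equal(isom_force_length(1 - mtu$CE$dW_asc, mtu), exp(-1))
  expect_equal(isom_force_length(1 + mtu$CE$dW_des, mtu), exp(-1))
  # continuity at the limb junction
  expect_equal(isom_force_length(1 - 1e-12, mtu),
               isom_force_length(1 + 1e-12, mtu), tolerance = 1e-9)
  expect_error(isom_force_length(0, mtu))
})

test_that("CE force is continuous at zero velocity with value a*F_isom*F_max", {
  for (l in c(0.6, 0.85, 1.0, 1.15)) {
    for (a in c(0.05, 0.15, 0.6, 1)) {
      f0 <- ce_force(l, 0, a, mtu)
      expect_equal(f0, a * isom_force_length(l, mtu) * mtu$CE$F_max,
                   tolerance = 1e-12)
      expect_equal(ce_force(l, 1e-10, a, mtu), f0, tolerance = 1e-7)
      expect_equal(ce_force(l, -1e-10, a, mtu), f0, tolerance = 1e-7)
    }
  }
})

test_that("eccentric branch slope at zero velocity is S_e times the concentric slope", {
  h <- 1e-7
  for (l in c(0.6, 0.9, 1.1)) {
    for (a in c(0.1, 0.5, 1)) {
      s_con <- (ce_force(l, 0, a, mtu) - ce_force(l, -h, a, mtu)) / h
      s_ecc <- (ce_force(l, h, a, mtu) - ce_force(l, 0, a, mtu)) / h
      expect_equal(s_ecc / s_con, mtu$CE$S_e, tolerance = 1e-5)
    }
  }
})

test_that("eccentric force rises monotonically to the F_e plateau", {
  v <- seq(0, 40, by = 0.25)
  for (a in c(0.15, 1)) {
    f <- ce_force(0.9, v, a, mtu) / mtu$CE$F_max
    q <- a * isom_force_length(0.9, mtu)
    expect_true(all(diff(f) > 0))
    expect_true(all(f >= q - 1e-12 & f <= mtu$CE$F_e * q + 1e-12))
    # asymptote
    expect_equal(ce_force(0.9, 1e9, a, mtu) / mtu$CE$F_max,
                 mtu$CE$F_e * q, tolerance = 1e-6)
  }
})

test_that("concentric hyperbola reaches zero force at the maximal shortening velocity", {
  a <- 0.5; l <- 1
  hp <- preflexr:::hill_arel_brel(l, a, mtu)
  q <- a * isom_force_length(l, mtu)
  v_max <- -hp$B_rel * q / hp$A_rel
  expect_equal(ce_force(l, v_max, a, mtu), 0, tolerance = 1e-9)
  expect_equal(ce_force(l, 2 * v_max, a, mtu), 0)   # clamped beyond
  expect_error(ce_force(l, 0, 1.2, mtu))
})

test_that("PEE is slack below its rest length and follows the power law above", {
  L0 <- mtu$PEE$L_PEE0
  expect_equal(parallel_elastic_force(L0, mtu), 0)
  expect_equal(parallel_elastic_force(0.7 * L0, mtu), 0)
  d <- 0.03
  ratio <- parallel_elastic_force(L0 + 2 * d, mtu) /
    parallel_elastic_force(L0 + d, mtu)
  expect_equal(ratio, 2^mtu$PEE$nu_PEE, tolerance = 1e-10)
  # strictly increasing and continuous at the rest length
  l <- seq(L0 - 0.01, L0 + 0.2, by = 0.005)
  f <- parallel_elastic_force(l, mtu)
  expect_true(all(diff(f) >= 0))
  expect_lt(parallel_elastic_force(L0 + 1e-9, mtu), 1e-6)
})

test_that("serial elastic + damping force matches its defining pieces", {
  s <- mtu$SEE
  expect_equal(serial_element_force(s$l_SEE0, 0, 0, mtu), 0)
  expect_equal(serial_element_force(0.9 * s$l_SEE0, 0, 0, mtu), 0)
  # SDE damping coefficient at full load and zero load
  v <- 0.2
  f_slack <- serial_element_force(0.5 * s$l_SEE0, v, mtu$CE$F_max, mtu)
  expect_equal(f_slack, mtu$SDE$d_SE_max * v, tolerance = 1e-12)
  f0 <- serial_element_force(0.5 * s$l_SEE0, v, 0, mtu)
  expect_equal(f0, mtu$SDE$R_SE * mtu$SDE$d_SE_max * v, tolerance = 1e-12)
  # C1 continuity of the SEE at the nonlinear/linear transition
  l_t <- s$l_SEE0 * (1 + s$dU_SEE_nll)
  h <- 1e-7
  slope_lo <- (preflexr:::serial_elastic_force(l_t, mtu) -
                 preflexr:::serial_elastic_force(l_t - h, mtu)) / h
  slope_hi <- (preflexr:::serial_elastic_force(l_t + h, mtu) -
                 preflexr:::serial_elastic_force(l_t, mtu)) / h
  expect_equal(slope_lo, slope_hi, tolerance = 1e-4 * slope_hi)
  expect_error(serial_element_force(-0.01, 0, 0, mtu))
})

test_that("contraction velocity satisfies the force balance and the isometric fixed point", {
  l_CE <- 0.56 * mtu$CE$l_opt
  a <- 0.15
  # construct the MTU length whose SEE force balances the contractile side
  f <- ce_force(0.56, 0, a, mtu) + parallel_elastic_force(0.56, mtu)
  l_MTU <- l_CE + preflexr:::serial_elastic_inverse(f, mtu)
  expect_equal(ce_contraction_velocity(l_CE, a, l_MTU, 0, mtu), 0,
               tolerance = 1e-10)
  # residual property on assorted states
  set.seed(11)
  for (i in 1:25) {
    l_CE <- runif(1, 0.5, 1.2) * mtu$CE$l_opt
    a <- runif(1, 0.05, 1)
    l_MTU <- l_CE + mtu$SEE$l_SEE0 * (1 + runif(1, -0.01, 0.05))
    v_MTU <- runif(1, -0.8, 0.8)
    v <- ce_contraction_velocity(l_CE, a, l_MTU, v_MTU, mtu)
    f_con <- ce_force(l_CE / mtu$CE$l_opt, v / mtu$CE$l_opt, a, mtu) +
      parallel_elastic_force(l_CE / mtu$CE$l_opt, mtu)
    resid <- f_con - serial_element_force(l_MTU - l_CE, v_MTU - v, f_con, mtu)
    expect_lt(abs(resid), 1e-9 * mtu$CE$F_max)
  }
})

test_that("closed-form contraction velocity agrees with the bisection oracle", {
  set.seed(23)
  for (i in 1:200) {
    p <- if (i %% 2) mtu else mtu_const
    l_CE <- runif(1, 0.45, 1.25) * p$CE$l_opt
    a <- runif(1, 0.05, 1)
    l_MTU <- l_CE + p$SEE$l_SEE0 * (1 + runif(1, -0.02, 0.06))
    v_MTU <- runif(1, -1, 1)
    v <- ce_contraction_velocity(l_CE, a, l_MTU, v_MTU, p)
    v_or <- bisect_vce(l_CE, a, l_MTU, v_MTU, p)
    expect_lt(abs(v - v_or), 1e-6 * p$CE$l_opt)
  }
})

test_that("activation dynamics has the right fixed point, saturation and half-time", {
  expect_equal(activation_step(0.3, 0.3, 0.01, mtu), 0.3)
  # saturation from the floor under full stimulation
  a <- mtu$ACT$a_min
  expect_equal(activation_step(1, a, 5, mtu), 1, tolerance = 1e-9)
  # step-response half-time of the first-order lag is tau*log(2)
  a0 <- 0.2; u <- 0.8
  t_half <- mtu$ACT$tau_act * log(2)
  a_half <- activation_step(u, a0, t_half, mtu)
  expect_equal(a_half, (a0 + u) / 2, tolerance = 1e-10)
  # against a fine-step Euler oracle
  a_euler <- a0; dt <- 1e-6
  for (k in seq_len(round(0.02 / dt))) {
    a_euler <- a_euler + dt * (u - a_euler) / mtu$ACT$tau_act
  }
  expect_equal(activation_step(u, a0, 0.02, mtu), a_euler, tolerance = 1e-4)
  expect_error(activation_step(0.5, 0.5, 0, mtu))
})

test_that("force-length ascending limb fit recovers parameters", {
  l <- seq(0.55, 0.98, length.out = 30)
  f <- exp(-((1 - l) / 0.45)^1.5)
  fit <- fit_force_length_ascending(l, f)
  expect_equal(fit$dW_asc, 0.45, tolerance = 1e-6)
  expect_equal(fit$nu_asc, 1.5, tolerance = 1e-5)
  expect_lte(fit$rss, fit$rss_start)
  # noisy recovery within 5%
  set.seed(4)
  l2 <- seq(0.5, 0.99, length.out = 50)
  f2 <- exp(-((1 - l2) / 0.45)^1.5) + rnorm(50, 0, 0.01)
  fit2 <- fit_force_length_ascending(l2, f2)
  expect_lt(abs(fit2$dW_asc - 0.45) / 0.45, 0.05)
  expect_lt(abs(fit2$nu_asc - 1.5) / 1.5, 0.05)
  expect_error(fit_force_length_ascending(c(0.7, 0.8, 0.9), rep(0.5, 3)),
               "identifiable")
  expect_error(fit_force_length_ascending(c(0.7, 0.8), c(0.2, 0.4)))
})

test_that("parameter config round-trips through YAML", {
  p <- hopper_parameters(mtu = mtu_parameters(F_max = 12345, S_e = 1.8))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mtu_config(p, path)
  p2 <- read_mtu_config(path)
  expect_s3_class(p2, "hopper_parameters")
  expect_equal(p2$mtu$CE$F_max, 12345)
  expect_equal(p2$mtu$CE$S_e, 1.8)
  expect_equal(p2$l_MTU_ref, p$l_MTU_ref, tolerance = 1e-12)
  # unknown keys are rejected
  writeLines(c("CE:", "  F_max: 10", "  bogus_key: 1"), path)
  expect_error(read_mtu_config(path), "bogus_key")
})
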