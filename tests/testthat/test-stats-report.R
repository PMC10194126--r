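test_that("Shapiro-Wilk wrapper separates Gaussian, bimodal and degenerate samples", {
  expect_error(shapiro_wilk(c(1, 2)))
  expect_true(shapiro_wilk(rep(1, 10))$degenerate)
  set.seed(31)
  p_gauss <- replicate(100, shapiro_wilk(rnorm(50))$p)
  expect_gte(mean(p_gauss > 0.05), 0.90)
  p_bimod <- replicate(100,
                       shapiro_wilk(c(rnorm(25, -3, 0.3), rnorm(25, 3, 0.3)))$p)
  expect_gte(mean(p_bimod < 0.05), 0.90)
})

test_that("Friedman test: identical columns, fully ordered blocks, rank invariance", {
  m <- matrix(5, 4, 3)            # identical columns
  fr <- friedman_test(m)
  expect_equal(fr$chisq, 0)
  expect_equal(fr$p, 1)
  # n = 3 blocks all strictly ordered the same way -> chi-squared = 6
  m2 <- rbind(c(1, 2, 3), c(10, 20, 30), c(0.1, 0.5, 0.9))
  expect_equal(friedman_test(m2)$chisq, 6)
  # invariance under within-block monotone transforms
  m3 <- matrix(rnorm(27), 9, 3)
  expect_equal(friedman_test(m3)$chisq,
               friedman_test(exp(m3))$chisq)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)))
})

test_that("Friedman statistic agrees with stats::friedman.test on all small matrices", {
  # exhaustive over row-multisets of 4x3 matrices with entries in {1,2,3}
  # (the statistic is invariant under block permutation)
  rows <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  combos <- utils::combn(nrow(rows) + 3, 4)   # multisets via stars-and-bars
  n_checked <- 0L
  max_dchi <- max_dp <- 0
  for (j in seq_len(ncol(combos))) {
    ix <- combos[, j] - seq_len(4) + 1L       # multiset indices in 1..27
    m <- rows[ix, , drop = FALSE]
    if (all(apply(m, 1, function(r) length(unique(r))) == 1)) next
    ours <- friedman_test(m)
    ref <- suppressWarnings(stats::friedman.test(m))
    max_dchi <- max(max_dchi, abs(ours$chisq - unname(ref$statistic)))
    max_dp <- max(max_dp, abs(ours$p - ref$p.value))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 27000)
  expect_lt(max_dchi, 1e-10)
  expect_lt(max_dp, 1e-10)
})

test_that("sign test p-values equal the binomial closed form", {
  for (n in c(3, 5, 9, 12, 25)) {
    for (npos in 0:n) {
      x <- c(rep(1, npos), rep(-1, n - npos))
      st <- sign_test(x)
      expect_equal(st$p, sign_test_closed_form(npos, n), tolerance = 1e-12)
    }
  }
  # the printed worked case: 9 positive differences out of 9
  st <- sign_test(rep(1, 9))
  expect_equal(st$p, 2 * (1 / 2)^9)
  # ties are dropped; all ties flagged
  st2 <- sign_test(c(0, 0, 1, 1, -1))
  expect_equal(st2$n_effective, 3L)
  expect_true(sign_test(rep(0, 5))$all_ties)
})

test_that("pairwise post hoc applies Bonferroni over the number of pairs", {
  m <- cbind(a = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
             b = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
             c = c(0, 1, 2, 3, 4, 5, 6, 7, 8))
  ph <- pairwise_posthoc(m)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))
  expect_equal(ph$p_raw[ph$pair == "a vs b"], 2 * (1 / 2)^9)
  ties <- pairwise_posthoc(cbind(x = 1:4, y = 1:4))
  expect_true(ties$all_ties)
  phw <- pairwise_posthoc(m, method = "wilcoxon")
  expect_equal(nrow(phw), 3)
  expect_true(all(phw$p_adj <= 1))
})

test_that("Friedman type-I error is close to nominal under the null", {
  set.seed(77)
  rej <- replicate(2000, friedman_test(matrix(rnorm(27), 9, 3))$p < 0.05)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Cohen's d: thresholds, invariances and degenerate input", {
  x <- c(-1, 0, 1, 2); y <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(cohens_d(x, y)$d, mean(x - y) / sqrt((var(x) + var(y)) / 2))
  expect_equal(cohens_d(x, x)$d, 0)
  expect_equal(cohens_d(3 * x, 3 * y)$d, cohens_d(x, y)$d)
  # classification at the printed cut-offs
  expect_equal(cohens_d(c(1, 2, 3), c(0.5, 1.4, 2.3), paired = TRUE)$label,
               "large")
  expect_equal(cohens_d(c(1, 2, 3), c(0.5, 1.4, 2.3), paired = TRUE)$d, 6)
  expect_error(cohens_d(c(1, 1), c(2, 2)))
  expect_error(cohens_d(c(1, 2), c(1, 2), paired = TRUE))
})

test_that("the report covers the full design and survives degenerate metrics", {
  rep <- build_report(px_analysis())
  fr <- rep$friedman
  # one Friedman per metric x speed x activity (post_srs only dynamic)
  expect_equal(sum(fr$metric == "work"), 6)
  expect_equal(sum(fr$metric == "srs"), 6)
  expect_equal(sum(fr$metric == "post_srs"), 3)
  expect_equal(nrow(rep$posthoc), 15 * 3)
  expect_equal(nrow(rep$speed_comparison), 2 * 3 * 3)
  # all-zero metrics: no crash, nothing significant
  m0 <- px_analysis()$metrics
  m0$work <- 0; m0$srs <- 0; m0$post_srs <- ifelse(is.na(m0$post_srs), NA, 0)
  rep0 <- build_report(list(metrics = m0, work_diff = px_analysis()$work_diff))
  expect_true(all(rep0$friedman$chisq == 0))
  expect_false(any(rep0$friedman$significant))
  # incomplete designs are refused
  expect_error(build_report(list(metrics = m0[-1, ])), "missing")
})
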