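# Independent bisection oracle for the CE-velocity force balance.
bisect_vce <- function(l_CE, a, l_MTU, v_MTU, params,
                       lo = -3, hi = 3, tol = 1e-9) {
  l_opt <- params$CE$l_opt
  f <- function(v) {
    f_con <- ce_force(l_CE / l_opt, v / l_opt, a, params) +
      parallel_elastic_force(l_CE / l_opt, params)
    f_con - serial_element_force(l_MTU - l_CE, v_MTU - v, f_con, params)
  }
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Exact two-sided sign-test p-value from the binomial closed form.
sign_test_closed_form <- function(npos, n) {
  x <- min(npos, n - npos)
  if (2 * x == n) return(1)
  p <- 2 * sum(choose(n, 0:x)) / 2^n
  min(1, p)
}

# Work of a piecewise-linear force-length profile, by the closed-form
# sum of trapezoid areas evaluated segment by segment from the knots.
piecewise_linear_work <- function(l_knots, f_knots) {
  stopifnot(length(l_knots) == length(f_knots))
  sum(diff(l_knots) * (head(f_knots, -1) + tail(f_knots, -1)) / 2)
}
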