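# Shared expensive fixtures, computed once per test run and cached.
.px_cache <- new.env(parent = emptyenv())

px_cached <- function(name, expr) {
  if (!exists(name, envir = .px_cache)) {
    assign(name, force(expr), envir = .px_cache)
  }
  get(name, envir = .px_cache)
}

px_params <- function() px_cached("params", hopper_parameters())

px_limit_cycle <- function() {
  px_cached("limit_cycle", find_limit_cycle(px_params()))
}

px_strides <- function() {
  px_cached("strides", {
    lc <- px_limit_cycle()
    sapply(c("up", "none", "down"), simulate_scenario,
           params = px_params(), limit_cycle = lc, simplify = FALSE)
  })
}

px_trajectories <- function() {
  px_cached("trajectories", {
    out <- list()
    for (sc in names(px_strides())) {
      dyn <- extract_lengthening(px_strides()[[sc]])
      out[[paste0(sc, ".dynamic")]] <- dyn
      out[[paste0(sc, ".quasistatic")]] <- make_quasistatic(dyn, 80, fs = 1e3)
    }
    out
  })
}

px_session <- function() {
  px_cached("session", generate_experiment(px_trajectories(), seed = 7))
}

px_analysis <- function() {
  px_cached("analysis", analyze_session(px_session()))
}

# a short synthetic lengthening ramp used by fiber/analysis unit tests:
# constant stretch velocity from l0, preflex-like timing
ramp_trajectory <- function(v_norm = 4, l0 = 0.56, duration = 0.12,
                            fs = 1e4, scenario = "none",
                            speed = "dynamic") {
  t <- seq(0, duration, by = 1 / fs)
  ce_trajectory(t, l0 + v_norm * t, rep(v_norm, length(t)),
                u = 0.15, scenario = scenario, speed_condition = speed)
}
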