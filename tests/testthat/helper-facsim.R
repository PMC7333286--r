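# shared fixtures, all built in code

# classic two-component Lotka-Volterra system in the term grammar
lv_spec <- function(alpha = 1, beta = 0.5, delta = 0.5, gamma = 1,
                    prey0 = 2, pred0 = 1) {
  system_spec(
    components = list(
      component("prey", initial_value = prey0, lower_bound = 0),
      component("pred", initial_value = pred0, lower_bound = 0)),
    terms = list(
      term("prey", "linear", "prey", "alpha", +1),
      term("prey", "bilinear", c("prey", "pred"), "beta", -1),
      term("pred", "bilinear", c("prey", "pred"), "delta", +1),
      term("pred", "constant_decay", coefficient = "gamma")),
    parameters = parameter_set(c(alpha = alpha, beta = beta,
                                 delta = delta, gamma = gamma)))
}

# single state with pure exponential decay
decay_spec <- function(lambda = 0.3, x0 = 2) {
  system_spec(
    components = list(component("x", initial_value = x0, lower_bound = 0)),
    terms = list(term("x", "constant_decay", coefficient = "lambda")),
    parameters = parameter_set(c(lambda = lambda)))
}

# wrap an arbitrary matrix as a trajectory for feature extraction
synthetic_trajectory <- function(times, states) {
  structure(list(times = times,
                 states = as.matrix(states),
                 exogenous = matrix(numeric(0), nrow = length(times),
                                    ncol = 0),
                 meta = list(solver = "synthetic", dt_out = times[2] - times[1],
                             t_max = times[length(times)], plan = NULL)),
            class = "facsim_trajectory")
}

# scenario runs are deterministic and expensive (especially the Euler
# oracle), so cache them across tests within the session
.scenario_cache <- new.env(parent = emptyenv())
scenario_run <- function(name, solver = "rk_adaptive", euler_dt = 1e-4) {
  key <- paste(name, solver, euler_dt, sep = "/")
  if (is.null(.scenario_cache[[key]])) {
    sc <- make_scenario(name)
    .scenario_cache[[key]] <- list(
      spec = sc$spec, plan = sc$plan,
      traj = simulate_system(sc$spec, sc$plan, solver = solver,
                             euler_dt = euler_dt))
  }
  .scenario_cache[[key]]
}

all_passed <- function(checks) all(vapply(checks, `[[`, TRUE, "passed"))
check_ids <- function(checks) vapply(checks, `[[`, "", "check_id")
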