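test_that("evaluate_rhs matches hand arithmetic on the prey-predator pair", {
  spec <- lv_spec(alpha = 1, beta = 0.5, delta = 0.5, gamma = 1)
  d <- evaluate_rhs(spec, c(prey = 2, pred = 1), t = 0)
  expect_equal(unname(d), c(1.0, 0.0), tolerance = 1e-15)
})

test_that("homogeneous system: zero state with zero forcing gives zero RHS", {
  spec <- build_reference_model(stimulus_level = 0)
  expect_equal(unname(evaluate_rhs(spec, rep(0, 6), t = 0)), rep(0, 6),
               tolerance = 1e-15)
  aug <- build_reference_model(variant = "reappraisal_augmented",
                               stimulus_level = 0)
  expect_equal(unname(evaluate_rhs(aug, rep(0, 7), t = 3)), rep(0, 7),
               tolerance = 1e-15)
})

test_that("evaluate_rhs rejects a state of the wrong length", {
  spec <- build_reference_model()
  expect_error(evaluate_rhs(spec, rep(0, 4), t = 0), "length")
})

test_that("zero RHS gives a constant trajectory", {
  spec <- lv_spec()
  spec$parameters <- parameter_set(c(alpha = 0, beta = 0, delta = 0,
                                     gamma = 0))
  traj <- simulate_system(spec, t_max = 10, dt_out = 0.5)
  expect_true(all(traj$states[, "prey"] == 2))
  expect_true(all(traj$states[, "pred"] == 1))
})

test_that("pure decay reproduces the closed form with both solvers", {
  spec <- decay_spec(lambda = 0.3, x0 = 2)
  traj <- simulate_system(spec, t_max = 10, dt_out = 0.1)
  expect_equal(traj$states[, "x"], 2 * exp(-0.3 * traj$times),
               tolerance = 1e-6)
  eul <- simulate_system(spec, t_max = 10, dt_out = 0.1, solver = "euler",
                         euler_dt = 1e-4)
  expect_equal(eul$states[, "x"], 2 * exp(-0.3 * eul$times),
               tolerance = 1e-4)
})

test_that("trajectories are clean: uniform grid, finite, non-negative", {
  for (name in c("baseline", "exposure", "reappraisal", "cbt")) {
    tr <- scenario_run(name)$traj
    expect_identical(tr$times[1], 0)
    expect_equal(diff(tr$times), rep(0.05, length(tr$times) - 1),
                 tolerance = 1e-9)
    expect_true(all(is.finite(tr$states)))
    expect_true(all(tr$states >= 0))
    expect_true(all(tr$states[, "cred_cat"] <= 1))
  }
})

test_that("output grid refinement is sampling, not dynamics", {
  sc <- make_scenario("exposure")
  a <- simulate_system(sc$spec, sc$plan, t_max = 20, dt_out = 0.1)
  b <- simulate_system(sc$spec, sc$plan, t_max = 20, dt_out = 0.05)
  shared <- match(a$times, b$times)
  expect_false(anyNA(shared))
  expect_identical(a$states, b$states[shared, ])
})

test_that("solvers agree on a short horizon", {
  sc <- make_scenario("baseline")
  a <- simulate_system(sc$spec, sc$plan, t_max = 10, dt_out = 0.1)
  b <- simulate_system(sc$spec, sc$plan, t_max = 10, dt_out = 0.1,
                       solver = "euler", euler_dt = 1e-4)
  expect_lt(max(abs(a$states - b$states)), 1e-3)
})

test_that("euler halving its step halves the error (first-order solver)", {
  spec <- decay_spec(lambda = 0.3, x0 = 2)
  exact <- function(tr) 2 * exp(-0.3 * tr$times)
  e1 <- simulate_system(spec, t_max = 10, dt_out = 0.5, solver = "euler",
                        euler_dt = 2e-3)
  e2 <- simulate_system(spec, t_max = 10, dt_out = 0.5, solver = "euler",
                        euler_dt = 1e-3)
  r <- max(abs(e1$states[, 1] - exact(e1))) /
    max(abs(e2$states[, 1] - exact(e2)))
  expect_equal(r, 2, tolerance = 0.05)
})

test_that("exposure clamp holds avoidance at exactly its clamp value", {
  run <- scenario_run("exposure")
  onset <- run$plan$exposure$onset
  after <- run$traj$times >= onset
  expect_true(all(run$traj$states[after, "Rb"] == 0))
  expect_true(all(run$traj$states[!after, "Rb"] > 0))
  # derivative entry is zero while clamped
  state <- run$traj$states[which(after)[10], ]
  d <- evaluate_rhs(run$spec, state, t = onset + 1, plan = run$plan)
  expect_identical(d[["Rb"]], 0)
})

test_that("missing coefficients and unknown variants are errors", {
  spec <- build_reference_model()
  spec$parameters$values <- spec$parameters$values[-1]
  expect_error(simulate_system(spec, t_max = 1),
               "missing coefficient")
  expect_error(build_reference_model(variant = "nonsense"))
})

test_that("non-finite dynamics are reported, not returned", {
  # explosive growth overflows well before t_max
  spec <- system_spec(
    components = list(component("x", initial_value = 1)),
    terms = list(term("x", "bilinear", c("x", "x"), "k", +1)),
    parameters = parameter_set(c(k = 5)))
  expect_error(simulate_system(spec, t_max = 50, solver = "euler",
                               euler_dt = 1e-3),
               "non-finite|underflow|finite")
  expect_error(simulate_system(spec, t_max = 50), ".")
})
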