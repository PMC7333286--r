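test_that("plan construction follows the scenario definitions", {
  p <- intervention_plan("baseline")
  expect_false(p$exposure$active)
  expect_false(p$reappraisal$active)

  p <- intervention_plan("cbt")
  expect_true(p$exposure$active && p$reappraisal$active)
  expect_identical(p$exposure$onset, p$reappraisal$onset)

  sc <- make_scenario("exposure", list(onset = 20))
  expect_identical(sc$plan$exposure$onset, 20)
  expect_identical(sc$plan$exposure$clamp_value, 0)

  expect_error(make_scenario("nonsense"))
  expect_error(make_scenario("baseline", list(parameters = c(bogus = 1))),
               "bogus")
  expect_error(make_scenario("baseline", list(typo = 1)), "typo")
  expect_error(intervention_plan("exposure", onset = -1))
})

test_that("inactive interventions leave the spec byte-identical", {
  spec <- build_reference_model()
  plan <- intervention_plan("baseline")
  expect_identical(spec_to_json(apply_exposure(spec, plan)),
                   spec_to_json(spec))
  expect_identical(spec_to_json(apply_reappraisal(spec, plan)),
                   spec_to_json(spec))
})

test_that("exposure releases panic: derivative jumps up at onset", {
  run <- scenario_run("exposure")
  onset <- run$plan$exposure$onset
  i <- max(which(run$traj$times < onset))
  state <- run$traj$states[i, ]
  d_before <- evaluate_rhs(run$spec, state, t = onset - 0.01, plan = run$plan)
  state_clamped <- state
  state_clamped["Rb"] <- 0
  d_after <- evaluate_rhs(run$spec, state_clamped, t = onset + 0.01,
                          plan = run$plan)
  expect_gt(d_after[["Re"]], d_before[["Re"]])
  # the benefits source term vanishes with the clamp
  expect_lt(d_after[["benefits"]], 0)
})

test_that("exposure requires an avoidance component", {
  spec <- decay_spec()
  expect_error(apply_exposure(spec, intervention_plan("exposure")), "Rb")
})

test_that("reappraisal with zero input is a no-op relative to baseline", {
  sc0 <- make_scenario("baseline")
  tr0 <- simulate_system(sc0$spec, sc0$plan, t_max = 30)
  sc1 <- make_scenario("reappraisal", list(input_level = 0))
  tr1 <- simulate_system(sc1$spec, sc1$plan, t_max = 30)
  shared <- colnames(tr0$states)
  # the onset breakpoint changes the adaptive step sequence, and local
  # O(tol) differences are amplified through the avoidance growth phase,
  # so equality holds at solver accuracy rather than machine precision
  expect_lt(max(abs(tr1$states[, shared] - tr0$states[, shared])), 1e-3)
  expect_true(all(tr1$states[, "cred_fun"] == 0))
})

test_that("functional credibility stays at rest before onset, grows after", {
  run <- scenario_run("reappraisal")
  onset <- run$plan$reappraisal$onset
  before <- run$traj$times < onset
  expect_true(all(run$traj$states[before, "cred_fun"] == 0))
  after_window <- run$traj$times >= onset & run$traj$times <= onset + 5
  expect_true(all(diff(run$traj$states[after_window, "cred_fun"]) >= 0))
})

test_that("cbt composes exposure and reappraisal in either order", {
  plan <- intervention_plan("cbt")
  spec <- build_reference_model()
  ab <- apply_reappraisal(apply_exposure(spec, plan), plan)
  ba <- apply_exposure(apply_reappraisal(spec, plan), plan)
  expect_identical(spec_to_json(ab), spec_to_json(ba))
  expect_identical(ab$clamps, ba$clamps)
  # and the composed system is what the bundled cbt scenario runs
  tr_manual <- simulate_system(ba, plan, t_max = 30)
  sc <- make_scenario("cbt")
  tr_bundled <- simulate_system(sc$spec, sc$plan, t_max = 30)
  expect_equal(tr_manual$states, tr_bundled$states, tolerance = 1e-12)
})

test_that("every scenario tracks baseline before the intervention onset", {
  base <- scenario_run("baseline")$traj
  for (name in c("exposure", "reappraisal", "cbt")) {
    run <- scenario_run(name)
    onset <- min(c(if (run$plan$exposure$active) run$plan$exposure$onset,
                   if (run$plan$reappraisal$active)
                     run$plan$reappraisal$onset))
    pre <- run$traj$times < onset
    shared <- colnames(base$states)
    expect_lt(max(abs(run$traj$states[pre, shared] -
                        base$states[pre, shared])), 1e-6)
  }
})

test_that("disable_growth exposure mode stops recruitment instead of clamping", {
  sc <- make_scenario("exposure", list(exposure_mode = "disable_growth"))
  tr <- simulate_system(sc$spec, sc$plan, t_max = 30)
  onset <- sc$plan$exposure$onset
  after <- tr$times >= onset + 0.05
  rb <- tr$states[after, "Rb"]
  expect_true(all(rb > 0))            # not clamped
  expect_true(all(diff(rb) <= 1e-9))  # but only decaying
})
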