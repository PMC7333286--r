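test_that("features of elementary series match closed forms", {
  tt <- seq(0, 50, by = 0.05)
  # constant series
  rep_c <- extract_features(synthetic_trajectory(tt,
    cbind(x = rep(3, length(tt)))))
  expect_identical(rep_c$peak_value, 3)
  expect_identical(rep_c$final_value, 3)
  expect_identical(rep_c$monotone_decreasing_from, 0)
  expect_identical(rep_c$time_to_half_max, 0)
  # exponential decay crosses half-max at ln 2
  rep_e <- extract_features(synthetic_trajectory(tt,
    cbind(x = exp(-tt))))
  expect_equal(rep_e$time_to_half_max, log(2), tolerance = 2 * 0.05)
  expect_identical(rep_e$monotone_decreasing_from, 0)
  # rising saturating series crosses half-max upward
  rep_r <- extract_features(synthetic_trajectory(tt,
    cbind(x = 1 - exp(-0.2 * tt))))
  expect_equal(rep_r$time_to_half_max, log(2) / 0.2, tolerance = 2 * 0.05)
})

test_that("monotone-decrease detection agrees with a brute-force scan", {
  eps <- 1e-3
  brute <- function(tt, x) {
    for (i in seq_along(x)) {
      if (all(diff(x[i:length(x)]) <= eps)) return(tt[i])
    }
    tt[length(x)]
  }
  tt <- seq(0, 20, by = 0.05)
  set.seed(99)
  for (k in 1:8) {
    x <- abs(cumsum(stats::rnorm(length(tt), sd = 0.05))) +
      ifelse(tt > stats::runif(1, 5, 15), -0.02 * tt, 0.02 * tt)
    got <- extract_features(synthetic_trajectory(tt, cbind(x = x)),
                            eps = eps)$monotone_decreasing_from
    expect_identical(got, brute(tt, x))
  }
})

test_that("features are invariant to output-grid refinement", {
  sc <- make_scenario("baseline")
  coarse <- extract_features(simulate_system(sc$spec, sc$plan,
                                             dt_out = 0.1))
  fine <- extract_features(simulate_system(sc$spec, sc$plan,
                                           dt_out = 0.05))
  for (field in c("peak_value", "final_value"))
    expect_equal(coarse[[field]], fine[[field]], tolerance = 1e-3)
  for (field in c("peak_time", "time_to_half_max"))
    expect_equal(coarse[[field]], fine[[field]], tolerance = 2 * 0.1)
})

test_that("a flat-zero trajectory cannot pass the persistence check", {
  tt <- seq(0, 50, by = 0.05)
  z <- matrix(0, length(tt), 6,
              dimnames = list(NULL, c("Rc", "Re", "Rb", "benefits",
                                      "costs", "cred_cat")))
  checks <- run_checks(extract_features(synthetic_trajectory(tt, z)),
                       "baseline")
  s1d <- checks[[which(check_ids(checks) == "s1d")]]
  expect_false(s1d$passed)
})

test_that("scenario/report mismatch guards: missing components fail, not pass", {
  tt <- seq(0, 50, by = 0.05)
  rep_x <- extract_features(synthetic_trajectory(tt,
    cbind(x = exp(-tt))))
  checks <- run_checks(rep_x, "baseline")
  expect_false(any(vapply(checks, `[[`, TRUE, "passed")))
})

test_that("check outcomes survive refining the grid and switching solver", {
  sc <- make_scenario("exposure")
  outcomes <- function(traj) {
    vapply(run_checks(extract_features(traj, sc$plan), "exposure"),
           `[[`, TRUE, "passed")
  }
  base <- outcomes(scenario_run("exposure")$traj)
  expect_identical(outcomes(simulate_system(sc$spec, sc$plan,
                                            dt_out = 0.025)), base)
  expect_identical(outcomes(simulate_system(sc$spec, sc$plan,
                                            solver = "euler",
                                            euler_dt = 1e-3)), base)
})

test_that("incongruence check is stable under horizon doubling", {
  sc <- make_scenario("baseline")
  r50 <- extract_features(scenario_run("baseline")$traj)
  r100 <- extract_features(simulate_system(sc$spec, sc$plan, t_max = 100))
  c50 <- known_incongruence_check(r50)
  c100 <- known_incongruence_check(r100)
  expect_identical(c50$passed, c100$passed)
})

test_that("check results export as a JSON report", {
  checks <- run_checks(extract_features(scenario_run("baseline")$traj),
                       "baseline")
  path <- withr::local_tempfile(fileext = ".json")
  checks_to_json(checks, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(doc, 4L)
  expect_identical(vapply(doc, `[[`, "", "check_id"),
                   c("s1a", "s1b", "s1c", "s1d"))
  expect_true(all(vapply(doc, `[[`, TRUE, "passed")))
})

test_that("short horizons are rejected rather than mis-measured", {
  sc <- make_scenario("exposure")
  tr <- simulate_system(sc$spec, sc$plan, t_max = 13, dt_out = 0.05)
  expect_error(extract_features(tr, sc$plan), "short")
})
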