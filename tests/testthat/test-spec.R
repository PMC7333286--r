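test_that("reference model self-validates and has the expected structure", {
  for (variant in c("scenario1", "reappraisal_augmented")) {
    spec <- build_reference_model(variant = variant)
    expect_identical(validate_spec(spec), character(0))
  }
  spec <- build_reference_model()
  expect_setequal(state_names(spec),
                  c("Rc", "Re", "Rb", "benefits", "costs", "cred_cat"))
  expect_identical(exogenous_names(spec), "Sd")
  aug <- build_reference_model(variant = "reappraisal_augmented")
  expect_true(all(c("cred_fun") %in% state_names(aug)))
  expect_true("reapp_in" %in% exogenous_names(aug))
})

test_that("prey-predator coupling signs are assertable from the term list", {
  spec <- build_reference_model()
  find_bilinear <- function(target) {
    Filter(function(tm) tm$target == target && tm$form == "bilinear" &&
             setequal(tm$sources, c("Re", "Rb")), spec$terms)
  }
  re_terms <- find_bilinear("Re")
  rb_terms <- find_bilinear("Rb")
  expect_length(re_terms, 1L)
  expect_length(rb_terms, 1L)
  expect_identical(re_terms[[1]]$sign, -1)  # avoidance relieves panic
  expect_identical(rb_terms[[1]]$sign, 1)   # panic recruits avoidance
})

test_that("augmented variant: more functional credibility means less catastrophizing drive", {
  aug <- build_reference_model(variant = "reappraisal_augmented")
  state <- initial_state(aug)
  state[] <- c(1, 1, 0.5, 0.2, 0.2, 0.8, 0)
  d0 <- evaluate_rhs(aug, state, t = 1)
  state["cred_fun"] <- 0.5
  d1 <- evaluate_rhs(aug, state, t = 1)
  expect_lt(d1[["Rc"]], d0[["Rc"]])
  # and strictly decreasing further
  state["cred_fun"] <- 0.9
  d2 <- evaluate_rhs(aug, state, t = 1)
  expect_lt(d2[["Rc"]], d1[["Rc"]])
})

test_that("validate_spec reports violations as data, naming the offender", {
  spec <- build_reference_model()
  # term targeting the exogenous stimulus
  bad <- spec
  bad$terms <- c(bad$terms, list(term("Sd", "linear", "Re",
                                      "panic_drive", +1)))
  v <- validate_spec(bad)
  expect_length(v, 1L)
  expect_match(v, "Sd")

  # negative decay coefficient
  bad <- spec
  bad$parameters$values[["panic_decay"]] <- -0.1
  v <- validate_spec(bad)
  expect_length(v, 1L)
  expect_match(v, "panic_decay")

  # missing forcing for an exogenous component
  bad <- spec
  bad$forcings$Sd <- NULL
  expect_match(validate_spec(bad), "forcing", all = FALSE)

  # duplicate names, unknown sources, bounds violations
  bad <- spec
  bad$components <- c(bad$components, bad$components[2])
  expect_match(validate_spec(bad), "duplicate", all = FALSE)
  bad <- spec
  bad$terms[[1]]$sources <- "nonexistent"
  expect_match(validate_spec(bad), "nonexistent", all = FALSE)
  bad <- spec
  bad$components[[7]]$initial_value <- 1.5  # cred_cat bounded by 1
  expect_match(validate_spec(bad), "upper_bound", all = FALSE)
})

test_that("zero couplings neutralize the RHS; decays alone give -decay*state", {
  spec <- build_reference_model(stimulus_level = 0)
  vals <- spec$parameters$values
  decays <- c("catastrophize_decay", "panic_decay", "avoidance_decay",
              "benefit_decay", "cost_decay", "credibility_decay")
  couplings <- setdiff(names(vals), decays)
  vals[couplings] <- 0
  spec$parameters <- parameter_set(vals)

  decay_by_comp <- unname(vals[decays])  # aligned with state order
  set.seed(4)
  for (i in 1:10) {
    state <- stats::runif(6, 0, 0.9)
    d <- evaluate_rhs(spec, state, t = i)
    expect_equal(unname(d), -decay_by_comp * state, tolerance = 1e-12)
  }
  # with decays zeroed too the whole RHS vanishes at any state
  vals[decays] <- 0
  spec$parameters <- parameter_set(vals)
  expect_equal(unname(evaluate_rhs(spec, stats::runif(6, 0, 3), 0)),
               rep(0, 6), tolerance = 1e-15)
})

test_that("forcing profiles are defined and non-negative over the horizon", {
  profiles <- list(
    forcing_constant(1.5),
    forcing_pulses(2, onsets = c(1, 10), offsets = c(4, 12)),
    forcing_piecewise(data.frame(time = c(0, 5, 20), level = c(0, 1, 0.5))))
  tt <- seq(0, 50, by = 0.37)
  for (f in profiles) {
    v <- forcing_value(f, tt)
    expect_length(v, length(tt))
    expect_false(anyNA(v))
    expect_true(all(v >= 0))
  }
  expect_identical(forcing_value(forcing_constant(1.5), tt),
                   rep(1.5, length(tt)))
  pw <- profiles[[3]]
  expect_identical(forcing_value(pw, c(0, 4.9, 5, 19, 25)),
                   c(0, 0, 1, 1, 0.5))
})

test_that("serialization round-trips byte-identically for bundled specs", {
  for (variant in c("scenario1", "reappraisal_augmented")) {
    spec <- build_reference_model(variant = variant)
    json1 <- spec_to_json(spec)
    spec2 <- spec_from_list(jsonlite::fromJSON(json1,
                                               simplifyVector = FALSE))
    json2 <- spec_to_json(spec2)
    expect_identical(json1, json2)
    # and through files
    p1 <- withr::local_tempfile(fileext = ".json")
    p2 <- withr::local_tempfile(fileext = ".json")
    write_spec(spec, p1)
    write_spec(read_spec(p1), p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("constructor contracts reject malformed terms", {
  expect_error(term("x", "linear", c("a", "b"), "k"), "1 source")
  expect_error(term("x", "bilinear", "a", "k"), "2 sources")
  expect_error(term("x", "modulated_linear", "a", "k"), "modulator")
  expect_error(parameter_set(c(1, 2)), "names")
  expect_error(forcing_pulses(1, onsets = 2, offsets = 1))
})
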