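#' Bundled reference parameterization
#'
#' Default rate constants and initial values for the reference
#' panic-disorder model. The values were obtained by the qualitative
#' calibration procedure this package implements (random search with
#' [calibrate_by_phenomena()] over clinically plausible ranges, followed by
#' rounding; seed recorded in the package sources), tuned until the
#' no-intervention and intervention scenarios reproduce the expected
#' clinical signatures checked by [run_checks()]. Every value is tagged
#' with provenance `"calibrated"` accordingly.
#'
#' Parameter roles (all rates per unit time, states in arbitrary
#' intensity units):
#' * `catastrophize_rate` / `credibility_gain` / `catastrophize_decay` —
#'   stimulus-driven growth of catastrophizing, its amplification by the
#'   credibility of the catastrophic interpretation, and its decay.
#' * `panic_drive` / `panic_relief` / `panic_decay` — catastrophizing
#'   drives panic; avoidance suppresses panic (the "prey" side of the
#'   predator-prey pair); intrinsic panic decay.
#' * `avoidance_growth` / `benefit_reinforcement` / `cost_inhibition` /
#'   `avoidance_decay` — panic recruits avoidance (the "predator" side),
#'   gain-modulated upward by perceived benefits and downward by
#'   perceived costs; intrinsic avoidance decay.
#' * `benefit_gain` / `benefit_decay`, `cost_gain` / `cost_decay` —
#'   accumulation and decay of perceived benefits (relief) and costs
#'   (withdrawal, work problems).
#' * `credibility_growth` / `credibility_decay` — avoidance prevents
#'   falsification, feeding the credibility of the catastrophic
#'   interpretation.
#' * `reappraisal_inhibition` / `credibility_competition` /
#'   `functional_growth` / `functional_decay` — the augmented variant:
#'   the credibility of the functional interpretation inhibits
#'   catastrophizing, competes with the catastrophic credibility, and is
#'   built up by reappraisal work.
#'
#' @param variant `"scenario1"` or `"reappraisal_augmented"`; the
#'   augmented parameters are a superset.
#' @return A [parameter_set()].
#' @export
default_parameters <- function(variant = c("scenario1",
                                           "reappraisal_augmented")) {
  variant <- match.arg(variant)
  vals <- c(
    catastrophize_rate   = 0.035,
    credibility_gain     = 30,
    catastrophize_decay  = 0.4,
    panic_drive          = 0.3,
    panic_relief         = 0.05,
    panic_decay          = 0.13,
    avoidance_growth     = 0.3,
    benefit_reinforcement = 0.4,
    cost_inhibition      = 0.3,
    avoidance_decay      = 0.1,
    benefit_gain         = 0.4,
    benefit_decay        = 0.25,
    cost_gain            = 0.06,
    cost_decay           = 0.025,
    credibility_growth   = 0.2,
    credibility_decay    = 0.12)
  if (variant == "reappraisal_augmented")
    vals <- c(vals,
              reappraisal_inhibition = 2.5,
              credibility_competition = 0.8,
              functional_growth = 0.3,
              functional_decay = 0.04)
  parameter_set(vals, "calibrated")
}

#' Default initial values of the reference model
#'
#' All responses start at rest except avoidant coping, which needs a
#' small strictly positive seed (`0.01`) because its bilinear growth term
#' cannot lift it off exactly zero, and the credibility of the
#' catastrophic interpretation, which starts at `0.9`: at intake the
#' patient already firmly believes the catastrophic interpretation, and
#' a high starting credibility is also what lets catastrophizing cross
#' half of its eventual credibility-amplified level early.
#'
#' @return Named numeric vector.
#' @export
default_initial_values <- function() {
  c(Rc = 0, Re = 0, Rb = 0.01, benefits = 0, costs = 0,
    cred_cat = 0.9, cred_fun = 0)
}

#' Build the reference panic-disorder model
#'
#' Constructs the formalized functional analysis of the bundled
#' hypothetical panic-disorder patient as a [system_spec()]. The
#' discriminant stimulus `Sd` (heart racing) is exogenous; catastrophic
#' interpretation `Rc`, panic `Re`, avoidant coping `Rb`, perceived
#' `benefits` and `costs`, and the credibility of the catastrophic
#' interpretation `cred_cat` are states. Panic and avoidance are coupled
#' like prey and predator: panic feeds avoidance growth, avoidance
#' suppresses panic. Benefits reinforce and costs inhibit avoidance
#' growth through gain modulation; avoidance feeds catastrophic
#' credibility (no falsification opportunities), which amplifies
#' stimulus-driven catastrophizing.
#'
#' The `reappraisal_augmented` variant adds the credibility of a
#' competing functional interpretation `cred_fun` (built up by an
#' exogenous reappraisal input `reapp_in`), an inhibitive term on
#' catastrophizing, and a competition term pulling `cred_cat` down.
#'
#' @param params Optional [parameter_set()]; defaults to
#'   [default_parameters()] for the variant. A scenario1-sized parameter
#'   set is accepted for the augmented variant, in which case the
#'   additional intervention parameters come from the defaults.
#' @param variant `"scenario1"` (six states) or
#'   `"reappraisal_augmented"` (seven states).
#' @param initial_values Optional named vector overriding
#'   [default_initial_values()] entries.
#' @param stimulus_level Constant level of the discriminant stimulus
#'   (default 1: the patient keeps encountering heart racing).
#' @return A validated `facsim_spec`.
#' @export
#' @examples
#' spec <- build_reference_model()
#' validate_spec(spec)  # character(0)
build_reference_model <- function(params = NULL,
                                  variant = c("scenario1",
                                              "reappraisal_augmented"),
                                  initial_values = NULL,
                                  stimulus_level = 1) {
  variant <- match.arg(variant)
  defaults <- default_parameters(variant)
  if (is.null(params)) {
    params <- defaults
  } else {
    stopifnot(inherits(params, "facsim_parameters"))
    missing <- setdiff(names(defaults$values), names(params$values))
    if (length(missing)) {
      base_only <- setdiff(missing, c("reappraisal_inhibition",
                                      "credibility_competition",
                                      "functional_growth",
                                      "functional_decay"))
      if (length(base_only))
        stop("parameter set is missing coefficient(s): ",
             paste(base_only, collapse = ", "), call. = FALSE)
      params <- parameter_set(
        c(params$values, defaults$values[missing]),
        c(params$provenance, defaults$provenance[missing]))
    }
  }

  iv <- default_initial_values()
  if (!is.null(initial_values)) {
    bad <- setdiff(names(initial_values), names(iv))
    if (length(bad)) stop("unknown initial value(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    iv[names(initial_values)] <- initial_values
  }

  aug <- variant == "reappraisal_augmented"
  comps <- list(
    component("Sd", "discriminant stimulus (heart racing)", "exogenous"),
    component("Rc", "catastrophizing", initial_value = iv[["Rc"]],
              lower_bound = 0),
    component("Re", "panic", initial_value = iv[["Re"]], lower_bound = 0),
    component("Rb", "avoidant coping", initial_value = iv[["Rb"]],
              lower_bound = 0),
    component("benefits", "perceived benefits of avoidance",
              initial_value = iv[["benefits"]], lower_bound = 0),
    component("costs", "perceived costs of avoidance",
              initial_value = iv[["costs"]], lower_bound = 0),
    component("cred_cat", "credibility of the catastrophic interpretation",
              initial_value = iv[["cred_cat"]], lower_bound = 0,
              upper_bound = 1))
  if (aug) {
    comps <- c(comps, list(
      component("cred_fun", "credibility of the functional interpretation",
                initial_value = iv[["cred_fun"]], lower_bound = 0,
                upper_bound = 1),
      component("reapp_in", "reappraisal input", "exogenous")))
  }

  terms <- list(
    # stimulus-driven catastrophizing, amplified by catastrophic credibility
    term("Rc", "modulated_linear", "Sd", "catastrophize_rate", +1,
         modulators = list(list(source = "cred_cat",
                                gain = "credibility_gain"))),
    term("Rc", "constant_decay", coefficient = "catastrophize_decay"),
    # panic: driven by catastrophizing, relieved by avoidance (prey side)
    term("Re", "linear", "Rc", "panic_drive", +1),
    term("Re", "bilinear", c("Re", "Rb"), "panic_relief", -1),
    term("Re", "constant_decay", coefficient = "panic_decay"),
    # avoidance: recruited by panic (predator side), gain-modulated by
    # perceived benefits (+) and costs (-)
    term("Rb", "bilinear", c("Re", "Rb"), "avoidance_growth", +1,
         modulators = list(
           list(source = "benefits", gain = "benefit_reinforcement"),
           list(source = "costs", gain = "cost_inhibition", sign = -1))),
    term("Rb", "constant_decay", coefficient = "avoidance_decay"),
    # reinforcement bookkeeping
    term("benefits", "bilinear", c("Re", "Rb"), "benefit_gain", +1),
    term("benefits", "constant_decay", coefficient = "benefit_decay"),
    term("costs", "linear", "Rb", "cost_gain", +1),
    term("costs", "constant_decay", coefficient = "cost_decay"),
    # lack of falsification: avoidance feeds catastrophic credibility
    term("cred_cat", "linear", "Rb", "credibility_growth", +1),
    term("cred_cat", "constant_decay", coefficient = "credibility_decay"))
  if (aug) {
    terms <- c(terms, list(
      # the functional interpretation inhibits catastrophizing in
      # confrontation with the stimulus ...
      term("Rc", "bilinear", c("cred_fun", "Sd"),
           "reappraisal_inhibition", -1),
      # ... and competes with the catastrophic interpretation
      term("cred_cat", "linear", "cred_fun", "credibility_competition", -1),
      term("cred_fun", "linear", "reapp_in", "functional_growth", +1),
      term("cred_fun", "constant_decay", coefficient = "functional_decay")))
  }

  forcings <- list(Sd = forcing_constant(stimulus_level))
  if (aug) forcings$reapp_in <- forcing_constant(0)

  system_spec(comps, terms, params, forcings, nonneg_clip = TRUE,
              variant = variant)
}
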