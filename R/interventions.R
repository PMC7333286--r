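#' Intervention plans
#'
#' An intervention plan describes which formalized CBT interventions act
#' on the system and when. Two interventions are available, mirroring
#' common clinical practice:
#'
#' * **Exposure** (behavioral): from `onset`, avoidant coping `Rb` is set
#'   to 0 and held there — the patient confronts the stimulus and
#'   response prevention blocks avoidance. Implemented as a hard clamp of
#'   the state; every term reading `Rb` sees the clamped value, so both
#'   the avoidance-mediated panic relief and the accrual of perceived
#'   benefits vanish.
#' * **Cognitive reappraisal** (cognitive): from `onset`, steady
#'   therapeutic input builds the credibility of a competing functional
#'   interpretation of the stimulus ("I simply had too much coffee"),
#'   which inhibits catastrophizing and competes with the catastrophic
#'   interpretation.
#'
#' The `cbt` scenario applies both simultaneously (identical onsets by
#' default).
#'
#' @param scenario_name One of `"baseline"`, `"exposure"`,
#'   `"reappraisal"`, `"cbt"`.
#' @param onset Intervention onset time; default 12.5 (a quarter of the
#'   default 50-unit horizon, leaving room to observe both the
#'   pre-intervention build-up and the post-intervention long-term
#'   behavior).
#' @param offset End of the exposure clamp, `NA` = permanent (the bundled
#'   scenarios keep exposure in place once introduced).
#' @param clamp_value Value avoidant coping is held at, default 0.
#' @param input_level Constant reappraisal input from onset, default 1.
#' @param exposure_mode `"clamp"` (default; the literal "set avoidant
#'   coping to 0" reading) or `"disable_growth"` (zero the avoidance
#'   growth coefficient from onset instead).
#' @return A `facsim_plan` list with fields `scenario_name`, `exposure`
#'   (`active`, `onset`, `offset`, `clamp_value`, `mode`) and
#'   `reappraisal` (`active`, `onset`, `input_level`).
#' @export
#' @examples
#' intervention_plan("exposure")
#' intervention_plan("cbt", onset = 20)
intervention_plan <- function(scenario_name = c("baseline", "exposure",
                                                "reappraisal", "cbt"),
                              onset = 12.5, offset = NA_real_,
                              clamp_value = 0, input_level = 1,
                              exposure_mode = c("clamp", "disable_growth")) {
  scenario_name <- match.arg(scenario_name)
  exposure_mode <- match.arg(exposure_mode)
  stopifnot(onset > 0)
  expo_on <- scenario_name %in% c("exposure", "cbt")
  reapp_on <- scenario_name %in% c("reappraisal", "cbt")
  structure(list(
    scenario_name = scenario_name,
    exposure = list(active = expo_on, onset = onset,
                    offset = as.numeric(offset),
                    clamp_value = as.numeric(clamp_value),
                    mode = exposure_mode),
    reappraisal = list(active = reapp_on, onset = onset,
                       input_level = as.numeric(input_level))),
    class = "facsim_plan")
}

#' Apply the exposure transformation to a spec
#'
#' When exposure is active, attaches the clamp rule (component `Rb` held
#' at `clamp_value` from onset to offset) that the integrator enforces
#' exactly; in `"disable_growth"` mode, the avoidance growth coefficient
#' is zeroed from onset instead. When exposure is inactive the spec is
#' returned unchanged (byte-identical serialization).
#'
#' @param spec A `facsim_spec` containing an `Rb` component.
#' @param plan An [intervention_plan()].
#' @return The (possibly) transformed spec.
#' @export
apply_exposure <- function(spec, plan) {
  if (is.null(plan) || !isTRUE(plan$exposure$active)) return(spec)
  if (!"Rb" %in% state_names(spec))
    stop("spec has no avoidant-coping component 'Rb' to expose",
         call. = FALSE)
  ex <- plan$exposure
  to <- if (is.na(ex$offset)) Inf else ex$offset
  if (ex$mode == "clamp") {
    rule <- list(component = "Rb", from = ex$onset, to = to,
                 value = ex$clamp_value)
    already <- any(vapply(spec$clamps %||% list(), identical, TRUE,
                          y = rule))
    if (!already) spec$clamps <- c(spec$clamps %||% list(), list(rule))
  } else {
    # disable_growth: growth parameter switched off from onset, realized
    # as a coefficient schedule the integrator applies at the breakpoint
    spec$coef_schedule <- c(spec$coef_schedule %||% list(),
                            list(list(parameter = "avoidance_growth",
                                      from = ex$onset, to = to, value = 0)))
  }
  spec
}

#' Apply the cognitive-reappraisal transformation to a spec
#'
#' Upgrades a reference scenario-1 spec to the reappraisal-augmented
#' variant (adding the `cred_fun` state with its inhibitive and
#' competition couplings) and wires the reappraisal input forcing: 0
#' before onset, `input_level` from onset on. Inactive plans return the
#' spec unchanged.
#'
#' @inheritParams apply_exposure
#' @return The transformed spec.
#' @export
apply_reappraisal <- function(spec, plan) {
  if (is.null(plan) || !isTRUE(plan$reappraisal$active)) return(spec)
  if (!"cred_fun" %in% state_names(spec)) {
    if (identical(spec$variant, "scenario1")) {
      iv <- initial_state(spec)
      spec2 <- build_reference_model(spec$parameters,
                                     variant = "reappraisal_augmented",
                                     initial_values = iv,
                                     stimulus_level = spec$forcings$Sd$level)
      spec2$clamps <- spec$clamps
      spec2$coef_schedule <- spec$coef_schedule
      spec <- spec2
    } else {
      stop("reappraisal requires the reappraisal-augmented model variant",
           call. = FALSE)
    }
  }
  rp <- plan$reappraisal
  spec$forcings$reapp_in <- forcing_piecewise(
    data.frame(time = c(0, rp$onset), level = c(0, rp$input_level)))
  spec
}

#' Resolve a bundled scenario
#'
#' Returns the fully resolved spec and plan for one of the four bundled
#' scenarios. Overrides may adjust parameter values (`parameters`, a
#' named numeric vector), initial values (`initial_values`), and the plan
#' fields `onset`, `offset`, `clamp_value`, `input_level`,
#' `exposure_mode`.
#'
#' @param name Scenario name: `"baseline"` (no intervention),
#'   `"exposure"`, `"reappraisal"`, or `"cbt"` (both, simultaneous).
#' @param overrides Named list of overrides, see Details.
#' @return List with elements `spec` and `plan`.
#' @export
#' @examples
#' sc <- make_scenario("exposure", list(onset = 20))
#' sc$plan$exposure$onset
make_scenario <- function(name = c("baseline", "exposure", "reappraisal",
                                   "cbt"),
                          overrides = list()) {
  name <- match.arg(name)
  known <- c("parameters", "initial_values", "onset", "offset",
             "clamp_value", "input_level", "exposure_mode")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  variant <- if (name %in% c("reappraisal", "cbt"))
    "reappraisal_augmented" else "scenario1"
  params <- default_parameters(variant)
  if (!is.null(overrides$parameters)) {
    ov <- overrides$parameters
    bad <- setdiff(names(ov), names(params$values))
    if (length(bad))
      stop("override references unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    vals <- params$values
    vals[names(ov)] <- as.numeric(ov)
    prov <- params$provenance
    prov[names(ov)] <- "user"
    params <- parameter_set(vals, prov)
  }
  spec <- build_reference_model(params, variant = variant,
                                initial_values = overrides$initial_values)

  plan_args <- overrides[intersect(names(overrides),
                                   c("onset", "offset", "clamp_value",
                                     "input_level", "exposure_mode"))]
  plan <- do.call(intervention_plan, c(list(scenario_name = name),
                                       plan_args))
  list(spec = spec, plan = plan)
}

#' @export
print.facsim_plan <- function(x, ...) {
  cat("<facsim intervention plan> scenario:", x$scenario_name, "\n")
  if (x$exposure$active)
    cat("  exposure: onset", x$exposure$onset, "clamp",
        x$exposure$clamp_value, "mode", x$exposure$mode, "\n")
  if (x$reappraisal$active)
    cat("  reappraisal: onset", x$reappraisal$onset, "input",
        x$reappraisal$input_level, "\n")
  if (!x$exposure$active && !x$reappraisal$active)
    cat("  no active interventions\n")
  invisible(x)
}
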