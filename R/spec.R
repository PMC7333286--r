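#' Declarative specification of an idiographic dynamical system
#'
#' A case conceptualization is formalized as a set of named components
#' (system variables), typed interaction terms between them, a parameter
#' set, and forcing profiles for exogenous components. The resulting
#' specification object is a plain, serializable description of the system
#' of coupled ordinary differential equations; it is compiled to a
#' right-hand-side function by [simulate_system()].
#'
#' @name facsim_spec
#' @keywords internal
NULL

#' Define a system component
#'
#' Components are the variables of the formalized case conceptualization:
#' either `state` components, whose time course is governed by the
#' differential equations built from the term list, or `exogenous`
#' components (such as the discriminant stimulus), whose value is read
#' from a [forcing profile][forcing_constant].
#'
#' @param name Short unique identifier, e.g. `"Re"` for the emotional
#'   response (panic) or `"Rb"` for the behavioral response (avoidance).
#' @param label Human-readable name; defaults to `name`.
#' @param role `"state"` or `"exogenous"`.
#' @param initial_value Non-negative starting intensity (arbitrary units;
#'   the units of clinical system variables are not assumed meaningful).
#' @param lower_bound,upper_bound Optional hard bounds the simulator clips
#'   to (e.g. `[0, 1]` for credibility components read as degrees of
#'   belief). `NA` means unbounded on that side.
#' @return A `facsim_component` list.
#' @export
#' @examples
#' component("Re", "panic", initial_value = 0)
#' component("cred_cat", "credibility of the catastrophic interpretation",
#'           initial_value = 0.5, lower_bound = 0, upper_bound = 1)
component <- function(name, label = name, role = c("state", "exogenous"),
                      initial_value = 0, lower_bound = NA_real_,
                      upper_bound = NA_real_) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(initial_value), length(initial_value) == 1L)
  structure(list(name = name, label = label, role = role,
                 initial_value = as.numeric(initial_value),
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound)),
            class = "facsim_component")
}

#' Define an interaction term
#'
#' Terms are the typed building blocks of the differential equations.
#' Every term contributes `sign * coefficient * <kernel>` to the
#' derivative of its target, where the kernel depends on `form`:
#'
#' * `linear` — the value of the single source component.
#' * `bilinear` — the product of two source components (the
#'   Lotka-Volterra style coupling used for the panic/avoidance
#'   predator-prey pair).
#' * `modulated_linear` — the first source scaled by
#'   `(1 + gain * modulator)` for each modulator; the combined
#'   modulation factor is floored at 0 so reinforcement/inhibition can
#'   silence a pathway but never reverse its sign.
#' * `constant_decay` — sugar for a negative linear self-term
#'   (exponential decay back to zero).
#'
#' Modulators may also be attached to `bilinear` terms; the kernel is then
#' `source1 * source2 * max(0, 1 + sum(gain_i * modulator_i))`, which is how
#' perceived benefits reinforce and perceived costs inhibit the growth of
#' avoidant coping.
#'
#' @param target Name of the state component whose derivative the term
#'   feeds.
#' @param form One of `"linear"`, `"bilinear"`, `"modulated_linear"`,
#'   `"constant_decay"`.
#' @param sources Character vector of 1-2 source component names
#'   (ignored for `constant_decay`, which always reads its target).
#' @param coefficient Name of the parameter holding the rate constant.
#' @param sign `+1` or `-1`.
#' @param modulators Optional list of `list(source = <component>,
#'   gain = <parameter name>, sign = +1/-1)` entries; `sign` (default
#'   `+1`) sets whether the modulator reinforces or inhibits, so gain
#'   parameters themselves stay non-negative.
#' @return A `facsim_term` list.
#' @export
term <- function(target, form = c("linear", "bilinear", "modulated_linear",
                                  "constant_decay"),
                 sources = character(), coefficient, sign = 1,
                 modulators = list()) {
  form <- match.arg(form)
  stopifnot(sign %in% c(-1, 1), is.character(coefficient),
            length(coefficient) == 1L)
  if (form == "constant_decay") {
    sources <- target
    sign <- -1
  }
  n_src <- length(sources)
  if (form %in% c("linear", "modulated_linear") && n_src != 1L)
    stop("form '", form, "' requires exactly 1 source", call. = FALSE)
  if (form == "bilinear" && n_src != 2L)
    stop("form 'bilinear' requires exactly 2 sources", call. = FALSE)
  if (form == "modulated_linear" && length(modulators) == 0L)
    stop("form 'modulated_linear' requires at least one modulator",
         call. = FALSE)
  modulators <- lapply(modulators, function(m) {
    stopifnot(is.list(m), !is.null(m$source), !is.null(m$gain))
    msign <- if (is.null(m$sign)) 1 else as.numeric(m$sign)
    stopifnot(msign %in% c(-1, 1))
    list(source = as.character(m$source), gain = as.character(m$gain),
         sign = msign)
  })
  structure(list(target = target, form = form,
                 sources = as.character(sources),
                 coefficient = coefficient, sign = as.numeric(sign),
                 modulators = modulators),
            class = "facsim_term")
}

#' Parameter sets with provenance
#'
#' Parameters are the "tuning knobs" of a formalized idiographic theory:
#' rate constants tailored to the individual patient. Each value carries a
#' provenance tag recording whether it was transcribed from a published
#' source (`"supplement"`), obtained by qualitative calibration
#' (`"calibrated"`), or set by the user (`"user"`).
#'
#' @param values Named numeric vector of parameter values.
#' @param provenance Single tag or named character vector aligned with
#'   `values`.
#' @return A `facsim_parameters` list.
#' @export
parameter_set <- function(values, provenance = "user") {
  stopifnot(is.numeric(values), !is.null(names(values)),
            all(nzchar(names(values))))
  if (length(provenance) == 1L)
    provenance <- stats::setNames(rep(provenance, length(values)),
                                  names(values))
  stopifnot(all(provenance %in% c("supplement", "calibrated", "user")),
            identical(sort(names(provenance)), sort(names(values))))
  structure(list(values = values, provenance = provenance[names(values)]),
            class = "facsim_parameters")
}

# --- forcing profiles --------------------------------------------------

#' Forcing profiles for exogenous components
#'
#' Exogenous components (the discriminant stimulus, the reappraisal input)
#' are driven by deterministic time functions rather than differential
#' equations.
#'
#' @param level Non-negative level (for `forcing_constant`, the value at
#'   all times; for `forcing_pulses`, the value inside each pulse).
#' @param onsets,offsets Equal-length vectors of pulse start/end times.
#' @param breaks Data frame with columns `time` and `level`; the profile
#'   is a left-continuous step function holding `level` from each
#'   breakpoint onward (times before the first breakpoint yield 0).
#' @return A `facsim_forcing` list.
#' @export
forcing_constant <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0)
  structure(list(kind = "constant", level = as.numeric(level)),
            class = "facsim_forcing")
}

#' @rdname forcing_constant
#' @export
forcing_pulses <- function(level, onsets, offsets) {
  stopifnot(length(onsets) == length(offsets), all(offsets > onsets),
            level >= 0)
  structure(list(kind = "pulses", level = as.numeric(level),
                 onsets = as.numeric(onsets), offsets = as.numeric(offsets)),
            class = "facsim_forcing")
}

#' @rdname forcing_constant
#' @export
forcing_piecewise <- function(breaks) {
  breaks <- as.data.frame(breaks)
  stopifnot(all(c("time", "level") %in% names(breaks)),
            !is.unsorted(breaks$time, strictly = TRUE),
            all(breaks$level >= 0))
  structure(list(kind = "piecewise",
                 times = as.numeric(breaks$time),
                 levels = as.numeric(breaks$level)),
            class = "facsim_forcing")
}

#' Evaluate a forcing profile
#'
#' @param forcing A `facsim_forcing` object.
#' @param t Numeric vector of times.
#' @return Numeric vector of forcing values, defined and non-negative for
#'   every `t >= 0`.
#' @export
forcing_value <- function(forcing, t) {
  switch(forcing$kind,
    constant = rep(forcing$level, length(t)),
    pulses = {
      out <- numeric(length(t))
      for (k in seq_along(forcing$onsets))
        out[t >= forcing$onsets[k] & t < forcing$offsets[k]] <- forcing$level
      out
    },
    piecewise = {
      idx <- findInterval(t, forcing$times)
      ifelse(idx == 0, 0, forcing$levels[pmax(idx, 1L)])
    },
    stop("unknown forcing kind: ", forcing$kind))
}

#' Breakpoint times of a forcing profile (integration must not step over
#' discontinuities).
#' @noRd
forcing_breaks <- function(forcing) {
  switch(forcing$kind,
    constant = numeric(),
    pulses = sort(c(forcing$onsets, forcing$offsets)),
    piecewise = forcing$times)
}

# --- system spec -------------------------------------------------------

#' Assemble a system specification
#'
#' @param components List of [component()] definitions (order fixes the
#'   state vector layout and the trajectory column order).
#' @param terms List of [term()] definitions.
#' @param parameters A [parameter_set()].
#' @param forcings Named list mapping each exogenous component name to a
#'   forcing profile.
#' @param nonneg_clip Clip all states at zero during integration
#'   (intensities cannot be negative)? Default `TRUE`.
#' @param variant Optional tag recording which bundled model variant this
#'   spec was built from (used when an intervention needs to upgrade a
#'   reference spec).
#' @return A `facsim_spec` object.
#' @seealso [build_reference_model()], [validate_spec()],
#'   [simulate_system()]
#' @export
system_spec <- function(components, terms, parameters, forcings = list(),
                        nonneg_clip = TRUE, variant = NA_character_) {
  stopifnot(is.list(components), is.list(terms),
            inherits(parameters, "facsim_parameters"))
  spec <- structure(list(components = components, terms = terms,
                         parameters = parameters, forcings = forcings,
                         nonneg_clip = isTRUE(nonneg_clip),
                         variant = as.character(variant)),
                    class = "facsim_spec")
  spec
}

component_names <- function(spec) vapply(spec$components, `[[`, "", "name")
component_roles <- function(spec) vapply(spec$components, `[[`, "", "role")

#' State component names of a spec, in state-vector order
#' @param spec A `facsim_spec`.
#' @return Character vector.
#' @export
state_names <- function(spec) {
  component_names(spec)[component_roles(spec) == "state"]
}

#' @rdname state_names
#' @export
exogenous_names <- function(spec) {
  component_names(spec)[component_roles(spec) == "exogenous"]
}

#' Initial state vector of a spec
#' @param spec A `facsim_spec`.
#' @return Named numeric vector in state order.
#' @export
initial_state <- function(spec) {
  st <- spec$components[component_roles(spec) == "state"]
  stats::setNames(vapply(st, `[[`, 0, "initial_value"),
                  vapply(st, `[[`, "", "name"))
}

#' Validate a system specification
#'
#' Checks every structural invariant of the spec grammar and returns the
#' violations as data rather than raising: an empty character vector means
#' the spec is well-formed. Checked invariants include name uniqueness,
#' that no term targets an exogenous component, that every exogenous
#' component has a forcing profile, that sources/modulators/coefficients
#' resolve, that decay coefficients are strictly positive and coupling
#' coefficients non-negative, and that initial values respect declared
#' bounds.
#'
#' @param spec A `facsim_spec`.
#' @return Character vector of human-readable violation descriptions,
#'   each naming the offending component, term, or parameter.
#' @export
validate_spec <- function(spec) {
  v <- character()
  nm <- component_names(spec)
  roles <- component_roles(spec)
  if (anyDuplicated(nm))
    v <- c(v, paste0("duplicate component name(s): ",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  pv <- spec$parameters$values
  for (co in spec$components) {
    if (!is.na(co$lower_bound) && co$initial_value < co$lower_bound)
      v <- c(v, paste0("component ", co$name,
                       ": initial_value below lower_bound"))
    if (!is.na(co$upper_bound) && co$initial_value > co$upper_bound)
      v <- c(v, paste0("component ", co$name,
                       ": initial_value above upper_bound"))
    if (co$role == "exogenous" && is.null(spec$forcings[[co$name]]))
      v <- c(v, paste0("exogenous component ", co$name,
                       " has no forcing profile"))
  }
  for (i in seq_along(spec$terms)) {
    tm <- spec$terms[[i]]
    id <- paste0("term ", i, " (-> ", tm$target, ")")
    if (!tm$target %in% nm) {
      v <- c(v, paste0(id, ": unknown target"))
    } else if (roles[match(tm$target, nm)] != "state") {
      v <- c(v, paste0(id, ": targets exogenous component ", tm$target))
    }
    bad_src <- setdiff(tm$sources, nm)
    if (length(bad_src))
      v <- c(v, paste0(id, ": unknown source(s) ",
                       paste(bad_src, collapse = ", ")))
    coefs <- tm$coefficient
    for (m in tm$modulators) {
      if (!m$source %in% nm)
        v <- c(v, paste0(id, ": unknown modulator source ", m$source))
      coefs <- c(coefs, m$gain)
    }
    for (cf in coefs) {
      if (!cf %in% names(pv)) {
        v <- c(v, paste0(id, ": parameter '", cf, "' is not defined"))
      }
    }
    if (tm$coefficient %in% names(pv)) {
      val <- pv[[tm$coefficient]]
      is_decay <- tm$form == "constant_decay" ||
        (tm$form == "linear" && tm$sign < 0 &&
           length(tm$sources) == 1L && tm$sources[1] == tm$target)
      if (is_decay && val <= 0)
        v <- c(v, paste0("parameter ", tm$coefficient,
                         ": decay rate must be strictly positive"))
      if (!is_decay && val < 0)
        v <- c(v, paste0("parameter ", tm$coefficient,
                         ": coupling coefficient must be non-negative"))
    }
  }
  v
}

#' @export
print.facsim_spec <- function(x, ...) {
  cat("<facsim system spec>",
      if (!is.na(x$variant)) paste0(" variant: ", x$variant), "\n", sep = "")
  cat("  state components:    ", paste(state_names(x), collapse = ", "), "\n")
  cat("  exogenous components:", paste(exogenous_names(x), collapse = ", "),
      "\n")
  cat("  terms:", length(x$terms), "  parameters:",
      length(x$parameters$values), "\n")
  invisible(x)
}
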