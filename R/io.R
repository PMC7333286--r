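#' Load and resolve a run configuration
#'
#' Run configurations are JSON documents with the top-level keys
#' `scenario`, `components`, `terms`, `parameters`, `initial_values`,
#' `forcing`, `intervention`, `simulation`, and `seed`. Either a bundled
#' `scenario` name is given (with optional parameter/initial-value
#' overrides), or a full custom system is described via
#' `components`/`terms`/`parameters`/`forcing`. The schema is
#' fail-closed: unknown keys (at the top level, in the `intervention`
#' block, or in the `simulation` block) are errors naming the key, so a
#' typo like `solvr` cannot silently fall back to a default. An empty
#' document resolves to the all-defaults baseline run. All defaults are
#' filled in and recorded, so the resolved configuration fully
#' reproduces the run.
#'
#' @param path Path to a JSON config file.
#' @return A `facsim_config` list with fully resolved fields.
#' @seealso [resolve_config()], [run_config()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- if (!nzchar(trimws(txt))) list() else
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
             error = function(e)
               stop("config parse error in ", path, ": ",
                    conditionMessage(e), call. = FALSE))
  resolve_config(doc)
}

#' @rdname load_config
#' @param doc A (possibly partial) configuration as a list.
#' @export
resolve_config <- function(doc = list()) {
  known <- c("scenario", "components", "terms", "parameters",
             "initial_values", "forcing", "intervention", "simulation",
             "seed")
  bad <- setdiff(names(doc), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  sim_known <- c("t_max", "dt_out", "solver", "tol", "euler_dt")
  sim <- doc$simulation %||% list()
  bad <- setdiff(names(sim), sim_known)
  if (length(bad))
    stop("unknown simulation key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sim <- utils::modifyList(list(t_max = 50, dt_out = 0.05,
                                solver = "rk_adaptive", tol = 1e-8,
                                euler_dt = 1e-3), sim)
  for (k in c("t_max", "dt_out", "tol", "euler_dt"))
    sim[[k]] <- as.numeric(sim[[k]])
  sim <- sim[c("t_max", "dt_out", "solver", "tol", "euler_dt")]
  if (!sim$solver %in% c("rk_adaptive", "euler"))
    stop("unknown solver: ", sim$solver, call. = FALSE)

  iv_known <- c("scenario_name", "onset", "offset", "clamp_value",
                "input_level", "exposure_mode")
  iv <- doc$intervention %||% list()
  bad <- setdiff(names(iv), iv_known)
  if (length(bad))
    stop("unknown intervention key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  scenario <- doc$scenario %||% iv$scenario_name %||% "baseline"
  if (!scenario %in% c("baseline", "exposure", "reappraisal", "cbt"))
    stop("unknown scenario: ", scenario, call. = FALSE)
  iv$scenario_name <- NULL
  iv <- utils::modifyList(list(onset = 12.5, offset = NA, clamp_value = 0,
                               input_level = 1, exposure_mode = "clamp"),
                          iv)
  for (k in c("onset", "offset", "clamp_value", "input_level")) {
    v <- iv[[k]]
    iv[[k]] <- if (is.null(v) || (length(v) == 1L && is.na(v)))
      NA_real_ else as.numeric(v)
  }
  iv <- iv[c("onset", "offset", "clamp_value", "input_level",
             "exposure_mode")]

  custom <- !is.null(doc$components)
  if (custom && is.null(doc$terms))
    stop("custom system config needs both 'components' and 'terms'",
         call. = FALSE)

  params <- doc$parameters %||% list()
  if (length(params) && is.null(names(params)) &&
      all(vapply(params, function(p) is.list(p) && !is.null(p$name),
                 TRUE))) {
    # spec-serialization style [{name, value, provenance}] is accepted
    nm <- vapply(params, function(p) p$name, "")
    params <- stats::setNames(lapply(params, function(p) p$value), nm)
  }

  structure(list(scenario = scenario,
                 components = doc$components,
                 terms = doc$terms,
                 parameters = params,
                 initial_values = doc$initial_values %||% list(),
                 forcing = doc$forcing,
                 intervention = iv,
                 simulation = sim,
                 seed = doc$seed %||% NULL),
            class = "facsim_config")
}

#' Write a resolved configuration (reproducibility file)
#'
#' @param config A `facsim_config`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  doc <- unclass(config)
  doc <- doc[!vapply(doc, is.null, TRUE)]
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = I(17), pretty = TRUE,
                                           null = "null", na = "null")),
             path)
  invisible(path)
}

#' Build the spec and plan a configuration describes
#'
#' @param config A `facsim_config` from [load_config()] or
#'   [resolve_config()].
#' @return List with `spec` and `plan`.
#' @export
config_to_system <- function(config) {
  iv <- config$intervention
  if (!is.null(config$components)) {
    doc <- list(components = config$components, terms = config$terms,
                parameters = lapply(seq_along(config$parameters),
                                    function(i)
                                      list(name = names(config$parameters)[i],
                                           value = config$parameters[[i]],
                                           provenance = "user")),
                initial_values = config$initial_values,
                forcing = config$forcing, nonneg_clip = TRUE,
                variant = NULL)
    spec <- spec_from_list(doc)
    plan <- intervention_plan(config$scenario, onset = iv$onset,
                              offset = if (is.null(iv$offset) ||
                                           is.na(iv$offset)) NA_real_
                                       else iv$offset,
                              clamp_value = iv$clamp_value,
                              input_level = iv$input_level,
                              exposure_mode = iv$exposure_mode)
    return(list(spec = spec, plan = plan))
  }
  overrides <- list(onset = iv$onset, clamp_value = iv$clamp_value,
                    input_level = iv$input_level,
                    exposure_mode = iv$exposure_mode)
  if (!is.null(iv$offset) && !is.na(iv$offset))
    overrides$offset <- iv$offset
  if (length(config$parameters))
    overrides$parameters <- unlist(config$parameters)
  if (length(config$initial_values))
    overrides$initial_values <- unlist(config$initial_values)
  make_scenario(config$scenario, overrides)
}

#' Run a configuration end to end
#'
#' Simulates the configured scenario and (optionally) evaluates its
#' check suite.
#'
#' @param config A `facsim_config`.
#' @param checks Run the scenario check suite on the result?
#' @return List with `spec`, `plan`, `trajectory`, and (when requested)
#'   `checks`.
#' @export
run_config <- function(config, checks = FALSE) {
  sys <- config_to_system(config)
  sim <- config$simulation
  traj <- simulate_system(sys$spec, sys$plan, t_max = sim$t_max,
                          dt_out = sim$dt_out, solver = sim$solver,
                          tol = sim$tol, euler_dt = sim$euler_dt)
  out <- list(spec = sys$spec, plan = sys$plan, trajectory = traj)
  if (checks) {
    report <- extract_features(traj, sys$plan)
    out$checks <- run_checks(report, config$scenario)
  }
  out
}

#' Export a trajectory as CSV
#'
#' One row per output time; header `time,<state components in spec
#' order>,<exogenous components>`; values printed with 10 significant
#' digits. Identical runs export bit-identical files.
#'
#' @param traj A `facsim_trajectory`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
export_trajectory <- function(traj, path) {
  m <- cbind(time = traj$times, traj$states, traj$exogenous)
  lines <- c(paste(colnames(m), collapse = ","),
             apply(m, 1, function(r)
               paste(sprintf("%.10g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_trajectory
#' @param n_exogenous Number of trailing exogenous columns in the file
#'   (the reader cannot infer this from the header alone).
#' @export
read_trajectory <- function(path, n_exogenous = 1) {
  df <- utils::read.csv(path, check.names = FALSE)
  nc <- ncol(df)
  state_cols <- 2:(nc - n_exogenous)
  exo_cols <- if (n_exogenous > 0) (nc - n_exogenous + 1):nc else integer()
  structure(list(times = df[[1]],
                 states = as.matrix(df[, state_cols, drop = FALSE]),
                 exogenous = as.matrix(df[, exo_cols, drop = FALSE]),
                 meta = list(solver = NA_character_,
                             dt_out = if (nrow(df) > 1)
                               df[[1]][2] - df[[1]][1] else NA_real_,
                             t_max = df[[1]][nrow(df)], plan = NULL)),
            class = "facsim_trajectory")
}
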