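#' Compile a spec into a fast right-hand-side evaluator
#'
#' Terms are flattened into index/coefficient vectors so that one RHS
#' evaluation is a handful of vectorized operations. The evaluator works
#' on the combined vector `c(state, exogenous, 1)`; absent second sources
#' point at the trailing constant 1. All bundled forcing kinds are
#' piecewise constant, so exogenous values are fixed per integration
#' segment and passed in once.
#'
#' @noRd
compile_rhs <- function(spec) {
  sn <- state_names(spec)
  xn <- exogenous_names(spec)
  n <- length(sn)
  idx <- function(name) {
    i <- match(name, c(sn, xn))
    if (is.na(i)) stop("unknown component: ", name, call. = FALSE)
    i
  }
  pv <- spec$parameters$values
  pval <- function(name) {
    if (!name %in% names(pv))
      stop("parameter set missing coefficient: ", name, call. = FALSE)
    pv[[name]]
  }
  nt <- length(spec$terms)
  tgt <- integer(nt); s1 <- integer(nt); s2 <- integer(nt)
  cf <- numeric(nt)
  one <- n + length(xn) + 1L  # index of the trailing constant 1
  mods <- vector("list", nt)
  for (i in seq_len(nt)) {
    tm <- spec$terms[[i]]
    tgt[i] <- match(tm$target, sn)
    s1[i] <- idx(tm$sources[1])
    s2[i] <- if (length(tm$sources) >= 2L) idx(tm$sources[2]) else one
    cf[i] <- tm$sign * pval(tm$coefficient)
    if (length(tm$modulators))
      mods[[i]] <- list(
        midx = vapply(tm$modulators, function(m) idx(m$source), 0L),
        mg = vapply(tm$modulators, function(m) m$sign * pval(m$gain), 0))
  }
  modded <- which(!vapply(mods, is.null, TRUE))
  # accumulation matrix: derivative = acc %*% per-term contributions
  acc <- matrix(0, n, nt)
  acc[cbind(tgt, seq_len(nt))] <- 1

  lo <- vapply(spec$components[component_roles(spec) == "state"],
               `[[`, 0, "lower_bound")
  hi <- vapply(spec$components[component_roles(spec) == "state"],
               `[[`, 0, "upper_bound")
  if (spec$nonneg_clip) lo[is.na(lo)] <- 0

  clip <- function(y) {
    w <- which(!is.na(lo) & y < lo)
    if (length(w)) y[w] <- lo[w]
    w <- which(!is.na(hi) & y > hi)
    if (length(w)) y[w] <- hi[w]
    y
  }

  # frozen: indices of clamped state entries (derivative forced to 0).
  # Bounds act as a projection: the RHS is evaluated at the clipped
  # state and outward-pointing derivative components at a bound are
  # zeroed, so every solver integrates the same projected dynamics and
  # bounded states (e.g. credibilities in [0, 1]) cannot drift past
  # their bounds between output points.
  f <- function(y, exo, frozen = NULL) {
    yc <- clip(y)
    v <- c(yc, exo, 1)
    contrib <- cf * v[s1] * v[s2]
    for (j in modded) {
      m <- mods[[j]]
      contrib[j] <- contrib[j] * max(0, 1 + sum(m$mg * v[m$midx]))
    }
    d <- drop(acc %*% contrib)
    w <- which(!is.na(lo) & y <= lo & d < 0)
    if (length(w)) d[w] <- 0
    w <- which(!is.na(hi) & y >= hi & d > 0)
    if (length(w)) d[w] <- 0
    if (!is.null(frozen)) d[frozen] <- 0
    d
  }
  list(f = f, clip = clip, n = n, state_names = sn, exo_names = xn)
}

#' Evaluate the right-hand side of a spec at one state
#'
#' Sums all term contributions per target component at time `t`, reading
#' exogenous values from the forcing profiles. If an intervention plan
#' clamps a component at `t` (exposure holding avoidant coping at its
#' clamp value), that component's derivative entry is 0.
#'
#' @param spec A `facsim_spec`.
#' @param state Numeric vector in state-component order (names optional).
#' @param t Time point.
#' @param plan Optional [intervention_plan()].
#' @return Named derivative vector.
#' @export
#' @examples
#' spec <- build_reference_model()
#' evaluate_rhs(spec, rep(0, 6), t = 0)  # zero forcing would give zeros
evaluate_rhs <- function(spec, state, t, plan = NULL) {
  prep <- prepare_run(spec, plan, t_max = Inf)
  spec <- prep$spec
  rhs <- compile_rhs(effective_spec(spec, t))
  if (length(state) != rhs$n)
    stop("state has length ", length(state), " but spec has ", rhs$n,
         " state components", call. = FALSE)
  exo <- vapply(spec$forcings[rhs$exo_names], forcing_value, 0, t = t)
  frozen <- clamp_mask(prep$clamps, rhs$state_names, t)
  stats::setNames(rhs$f(as.numeric(state), exo, frozen), rhs$state_names)
}

clamp_mask <- function(clamps, sn, t) {
  if (!length(clamps)) return(NULL)
  frozen <- rep(FALSE, length(sn))
  for (cl in clamps)
    if (t >= cl$from && t <= cl$to) frozen[match(cl$component, sn)] <- TRUE
  if (any(frozen)) which(frozen) else NULL
}

# Dormand-Prince 5(4) coefficients
dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
dp_e <- c(71 / 57600, 0, -71 / 16695, 71 / 1920, -17253 / 339200, 22 / 525,
          -1 / 40)
dp_d <- c(-12715105075 / 11282082432, 0, 87487479700 / 32700410799,
          -10690763975 / 1880347072, 701980252875 / 199316789632,
          -1453857185 / 822651844, 69997945 / 29380423)

#' One integration segment with the adaptive Dormand-Prince pair.
#' Exogenous forcing and the clamp mask are constant over a segment;
#' output values at interior grid times come from the method's dense
#' output, so they do not depend on the output grid at all.
#' @noRd
rk_segment <- function(f, clip, y, t0, t1, exo, frozen, out_t, tol) {
  n <- length(y)
  out <- if (length(out_t)) matrix(NA_real_, length(out_t), n) else NULL
  oi <- 1L
  t <- t0
  h <- min(t1 - t0, 0.1)
  k1 <- f(y, exo, frozen)
  safety <- 0.9
  while (t < t1 - 1e-12 * max(1, abs(t1))) {
    h <- min(h, t1 - t)
    k <- matrix(0, n, 7)
    k[, 1] <- k1
    for (s in 2:6) {
      ys <- y + h * drop(k[, 1:(s - 1), drop = FALSE] %*% dp_a[[s - 1]])
      k[, s] <- f(ys, exo, frozen)
    }
    y1 <- y + h * drop(k[, 1:6] %*% dp_a[[6]])
    k[, 7] <- f(y1, exo, frozen)
    err_v <- h * drop(k %*% dp_e)
    sc <- tol + tol * pmax(abs(y), abs(y1))
    err <- sqrt(mean((err_v / sc)^2))
    if (!is.finite(err))
      stop("non-finite error estimate at t = ", signif(t, 6), call. = FALSE)
    if (err <= 1) {
      # accept; fill dense output for grid times inside (t, t+h]
      while (oi <= length(out_t) && out_t[oi] <= t + h + 1e-12) {
        theta <- (out_t[oi] - t) / h
        ydiff <- y1 - y
        bspl <- h * k[, 1] - ydiff
        r4 <- ydiff - h * k[, 7] - bspl
        r5 <- h * drop(k %*% dp_d)
        th1 <- 1 - theta
        out[oi, ] <- y + theta * (ydiff + th1 * (bspl + theta * (r4 + th1 * r5)))
        oi <- oi + 1L
      }
      t <- t + h
      y <- clip(y1)
      # FSAL reuse is only valid if clipping did not move the state
      k1 <- if (identical(y, y1)) k[, 7] else f(y, exo, frozen)
      h <- h * min(5, max(0.2, safety * err^(-0.2)))
    } else {
      h <- h * max(0.2, safety * err^(-0.2))
    }
    if (h < 1e-12)
      stop("step size underflow at t = ", signif(t, 6), call. = FALSE)
  }
  list(y = y, out = out)
}

euler_segment <- function(f, clip, y, t0, t1, exo, frozen, out_t, dt) {
  n_steps <- max(1L, as.integer(round((t1 - t0) / dt)))
  hh <- (t1 - t0) / n_steps
  out <- if (length(out_t)) matrix(NA_real_, length(out_t), length(y)) else NULL
  oi <- 1L
  # output times as step indices, so the hot loop stays branch-light
  out_i <- if (length(out_t)) pmin(n_steps,
                                   as.integer(round((out_t - t0) / hh)))
           else integer()
  next_out <- if (length(out_i)) out_i[1] else -1L
  for (i in seq_len(n_steps)) {
    y <- clip(y + hh * f(y, exo, frozen))
    if (i == next_out) {
      while (oi <= length(out_i) && out_i[oi] == i) {
        out[oi, ] <- y
        oi <- oi + 1L
      }
      next_out <- if (oi <= length(out_i)) out_i[oi] else -1L
    }
  }
  list(y = y, out = out)
}

#' Resolve interventions into the spec/clamp schedule used by the
#' integrator.
#' @noRd
prepare_run <- function(spec, plan, t_max) {
  if (is.null(plan)) plan <- intervention_plan("baseline")
  spec <- apply_reappraisal(spec, plan)
  spec <- apply_exposure(spec, plan)
  clamps <- spec$clamps %||% list()
  clamps <- lapply(clamps, function(cl) {
    cl$to <- min(cl$to %||% Inf, t_max, na.rm = TRUE)
    cl
  })
  list(spec = spec, plan = plan, clamps = clamps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply any active coefficient schedule entries (e.g. exposure in
#' disable_growth mode) to the parameter set at time t.
#' @noRd
effective_spec <- function(spec, t) {
  sched <- spec$coef_schedule
  if (!length(sched)) return(spec)
  for (sc in sched) {
    to <- sc$to %||% Inf
    if (t >= sc$from && t <= to)
      spec$parameters$values[[sc$parameter]] <- sc$value
  }
  spec
}

#' Simulate a formalized case conceptualization
#'
#' Integrates the system of differential equations described by `spec`
#' over `[0, t_max]` under an intervention plan. Intervention onsets and
#' offsets, and forcing breakpoints, are hard integration breakpoints:
#' the solver integrates up to the breakpoint, applies the state
#' transformation (e.g. setting avoidant coping to its clamp value), and
#' continues. Clamped components are held exactly at their clamp value.
#' The simulation is fully deterministic.
#'
#' @param spec A `facsim_spec` (see [build_reference_model()]).
#' @param plan An [intervention_plan()]; default baseline (no
#'   intervention).
#' @param t_max Simulation horizon (time units), default 50.
#' @param dt_out Output grid spacing, default 0.05. The grid samples the
#'   continuous solution; refining it does not change values at shared
#'   times.
#' @param solver `"rk_adaptive"` (Dormand-Prince 5(4) with dense output,
#'   the default) or `"euler"` (fixed-step explicit Euler, retained as a
#'   cross-validation oracle).
#' @param tol Relative = absolute tolerance of the adaptive solver,
#'   default `1e-8`.
#' @param euler_dt Step size for the Euler solver, default `1e-3`.
#' @return A `facsim_trajectory`: list with `times` (uniform grid from 0
#'   to `t_max`), `states` (matrix, one column per state component),
#'   `exogenous` (forcing values on the same grid), and `meta`.
#' @export
#' @examples
#' spec <- build_reference_model()
#' traj <- simulate_system(spec, t_max = 10)
#' head(traj$states)
simulate_system <- function(spec, plan = NULL, t_max = 50, dt_out = 0.05,
                            solver = c("rk_adaptive", "euler"), tol = 1e-8,
                            euler_dt = 1e-3) {
  solver <- match.arg(solver)
  stopifnot(t_max > 0, dt_out > 0)
  prep <- prepare_run(spec, plan, t_max)
  spec <- prep$spec
  plan <- prep$plan
  rhs <- compile_rhs(spec)

  times <- seq(0, t_max, by = dt_out)
  if (abs(times[length(times)] - t_max) > 1e-9)
    times <- c(times, t_max)

  # breakpoints: clamp windows, coefficient schedules, forcing
  # discontinuities
  brk <- unlist(lapply(spec$forcings, forcing_breaks))
  for (cl in prep$clamps) brk <- c(brk, cl$from, cl$to)
  for (sc in spec$coef_schedule %||% list())
    brk <- c(brk, sc$from, sc$to %||% Inf)
  brk <- sort(unique(c(0, t_max, brk[is.finite(brk) & brk > 0 &
                                       brk < t_max])))

  y <- unname(initial_state(spec))
  states <- matrix(NA_real_, length(times), rhs$n,
                   dimnames = list(NULL, rhs$state_names))
  states[1, ] <- rhs$clip(y)

  for (si in seq_len(length(brk) - 1L)) {
    t0 <- brk[si]; t1 <- brk[si + 1L]
    # forcing is piecewise constant: evaluate just inside the segment
    t_probe <- t0 + min(1e-9, (t1 - t0) / 2)
    if (length(spec$coef_schedule))
      rhs <- compile_rhs(effective_spec(spec, t_probe))
    exo <- vapply(spec$forcings[rhs$exo_names], forcing_value, 0,
                  t = t_probe)
    frozen <- clamp_mask(prep$clamps, rhs$state_names, t_probe)
    if (!is.null(frozen)) {
      for (cl in prep$clamps)
        if (t_probe >= cl$from && t_probe <= cl$to) {
          j <- match(cl$component, rhs$state_names)
          y[j] <- cl$value
          # the output point sitting exactly on the clamp onset belongs to
          # the clamped regime
          at_t0 <- which(abs(times - t0) <= 1e-12)
          if (length(at_t0)) states[at_t0, j] <- cl$value
        }
    }
    sel <- which(times > t0 + 1e-12 & times <= t1 + 1e-12)
    seg <- if (solver == "rk_adaptive") {
      rk_segment(rhs$f, rhs$clip, y, t0, t1, exo, frozen, times[sel], tol)
    } else {
      euler_segment(rhs$f, rhs$clip, y, t0, t1, exo, frozen, times[sel],
                    euler_dt)
    }
    y <- rhs$clip(seg$y)
    if (!is.null(frozen)) {
      for (cl in prep$clamps)
        if (t_probe >= cl$from && t_probe <= cl$to)
          y[match(cl$component, rhs$state_names)] <- cl$value
    }
    if (length(sel)) {
      m <- seg$out
      for (r in seq_len(nrow(m))) m[r, ] <- rhs$clip(m[r, ])
      if (!is.null(frozen)) {
        for (cl in prep$clamps)
          if (t_probe >= cl$from && t_probe <= cl$to)
            m[, match(cl$component, rhs$state_names)] <- cl$value
      }
      states[sel, ] <- m
    }
  }

  if (anyNA(states) || any(!is.finite(states)))
    stop("integration produced non-finite state values", call. = FALSE)

  exo_mat <- vapply(spec$forcings[rhs$exo_names],
                    function(fc) forcing_value(fc, times),
                    numeric(length(times)))
  exo_mat <- matrix(exo_mat, nrow = length(times),
                    dimnames = list(NULL, rhs$exo_names))

  structure(list(times = times, states = states, exogenous = exo_mat,
                 meta = list(spec_hash = spec_hash(spec), plan = plan,
                             solver = solver, dt_out = dt_out, tol = tol,
                             t_max = t_max, variant = spec$variant)),
            class = "facsim_trajectory")
}

#' @export
print.facsim_trajectory <- function(x, ...) {
  cat("<facsim trajectory> ", nrow(x$states), " points on [0, ",
      x$meta$t_max, "], solver ", x$meta$solver, "\n", sep = "")
  cat("  components:", paste(colnames(x$states), collapse = ", "), "\n")
  invisible(x)
}
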