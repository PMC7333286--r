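---
title: "Formalizing a case conceptualization: model, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formalizing a case conceptualization: model, calibration, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facsim)
```

## What this package models

A functional analysis (SORKC) explains maladaptive behavior through
conditioning: a discriminant stimulus evokes cognitive, emotional, and
behavioral responses, and the behavior is maintained by its
consequences. `facsim` treats such a case conceptualization as a small
dynamical system: every component becomes a state variable with a
differential equation assembled from a restricted grammar of terms
(`linear`, `bilinear`, `modulated_linear`, `constant_decay`). The
grammar is deliberately narrow — it covers what a clinician asserts in
a functional analysis (drives, decays, product interactions, gain
modulation) without becoming a general symbolic DSL.

The bundled reference system describes a hypothetical panic-disorder
patient. Its structural commitments:

* **Catastrophizing** is driven by the stimulus, amplified
  multiplicatively by the credibility of the catastrophic
  interpretation (`1 + gain * credibility`), and decays.
* **Panic and avoidance form a predator–prey pair.** Panic (prey) is
  driven by catastrophizing and consumed by avoidance; avoidance
  (predator) grows through a bilinear `panic * avoidance` term and
  decays. This is the standard Lotka–Volterra coupling, chosen because
  the clinical claim — more panic recruits more avoidance, more
  avoidance yields less panic — is exactly the prey–predator
  structure.
* **Benefits and costs modulate avoidance growth** as a gain factor
  `max(0, 1 + g_B*benefits − g_C*costs)`. Gain modulation (not an
  independent drive) is the right reading of "reinforcing or
  inhibiting the behavior": consequences scale the operant loop, they
  do not produce avoidance on their own. The floor at 0 lets
  inhibition silence the loop but never invert it into an
  avoidance-producing pathway.
* **Credibility of the catastrophic interpretation** grows with
  avoidance (no falsification opportunities) and is bounded in
  [0, 1], read as a degree of belief. State units are otherwise
  arbitrary intensities; the underlying theory does not operationalize
  its variables, so only orderings, ratios and qualitative shapes are
  meaningful.

Two interventions are formalized. **Exposure** sets avoidant coping to
zero from its onset — implemented literally as a clamp of the state
(the behavioral prescription), with the alternative reading
(`exposure_mode = "disable_growth"`, zeroing the avoidance growth
coefficient) available as a config switch. **Cognitive reappraisal**
introduces the credibility of a competing functional interpretation.
The wording "an inverse function of the latter" admits two readings:
an algebraic complement (`cred_fun = 1 − cred_cat`) or a dynamic state
coupled by competition. We model a *dynamic state* with an explicit
competition term pulling the catastrophic credibility down, because the
clinical claim has a time course — the functional interpretation must
*gain* credibility through therapeutic work before it can displace the
catastrophic one — and the lag between reappraisal input and avoidance
decline (check s3b) is only expressible with a dynamic state.
Reappraisal input is a constant drive from onset (steady therapeutic
work); the original account does not state its time course, and a
pulse train is configurable through the forcing grammar if wanted.
Exposure is permanent from onset by default (offset `NA`), matching
the long-term post-intervention behavior the scenarios examine.

## Parameters and initial values

All rates are per unit time; defaults sit on `default_parameters()`.
The defaults are **calibrated, not transcribed**: the original
supplement with exact equations and values was not available to this
implementation, so the package follows its own documented fallback —
`calibrate_by_phenomena()`, a seeded random search over clinically
plausible ranges scored by the number of passed baseline checks, which
is the reproducible version of "adjust parameters until the system
behaves as the case information leads one to expect". The shipped
values are a rounded full-pass point from that procedure; every value
carries provenance `"calibrated"`.

Two initial values deserve comment:

* `Rb(0) = 0.01`, not 0: the bilinear growth term cannot lift
  avoidance off exactly zero (a standard predator–prey requirement),
  so the patient starts with a vestigial avoidance tendency.
* `cred_cat(0) = 0.9`: at intake the patient already firmly believes
  the catastrophic interpretation. Besides being clinically faithful
  for a presenting panic patient, this choice reconciles two scenario
  signatures that conflict at low starting credibility: with strong
  credibility amplification, a low-credibility start makes
  catastrophizing reach half of its eventual amplified level only late
  (breaking the "catastrophizing rises before panic" ordering), while
  weak amplification leaves too much residual panic drive after
  exposure has eroded credibility (breaking the long-term panic
  decay). A high starting credibility gives the early half-max
  crossing and still lets exposure erode the drive.

## Simulation

The default solver is an adaptive Dormand–Prince 5(4) pair
(`rtol = atol = 1e-8`) with the method's standard dense output, so the
output grid is pure *sampling*: refining `dt_out` changes no value at
shared output times, bit for bit. A fixed-step explicit Euler
integrator is retained as an independent cross-validation oracle. The
model is non-stiff at the reference parameterization.

Numerical policies worth knowing:

* **Bounds as projection.** Non-negativity (and the [0, 1] credibility
  bounds) are enforced by evaluating the right-hand side at the
  clipped state and zeroing outward-pointing derivative components at
  a bound, plus post-step flooring. Both solvers therefore integrate
  the *same* projected dynamics. This is a documented approximation in
  place of event detection, adequate for qualitative acceptance.
* **Interventions are hard breakpoints.** Integration stops exactly at
  every onset/offset and forcing discontinuity, applies the state
  transformation, and restarts; clamped components are held exactly
  (the exposure scenario has avoidance identically 0 at every output
  time from onset on, not approximately 0).
* **Determinism.** There is no randomness in the dynamics; identical
  configurations produce bit-identical CSV exports. The only seeded
  randomness in the package is the calibration search, which uses a
  private RNG stream and restores the session RNG.

## Phenomena checks: what a green suite establishes

`extract_features()` quantifies the verbal trajectory descriptions:
peak, first crossing of half the global peak (upward for series
starting below it, downward for decay-from-peak series), long-term
level (mean of the final 5% of the horizon), pre-onset level,
short-term post-onset maximum (10% of the horizon), and the earliest
time from which a series is non-increasing within `eps = 1e-3`. The
check thresholds — panic "persists" at ≥ 50% of peak, "decays" to
< 20% (50% for reappraisal alone) of pre-onset, benefits "disappear"
to < 5% of peak — are explicit, deliberately loose conventions for
qualitative words; none of them is an empirical quantity, and all are
configurable.

A green suite establishes that the *formalized theory* reproduces the
expected qualitative signatures under the bundled parameterization. It
does not establish correspondence with any measured patient data (no
empirical time series enters the package anywhere), nor robustness of
the signatures across the whole plausible parameter space — the suite
is the calibration target, so passing it is evidence of internal
coherence, not external validity.

## Known limitations

* **Sustained panic.** Without intervention the simulated panic
  manifests and persists in the long term; real panic attacks spike
  and subside within minutes to hours. This incongruence between model
  and phenomenon is acknowledged in the source account and kept here
  as a *positive regression check*
  (`known_incongruence_check()`): the baseline final/peak panic ratio
  is asserted to stay ≥ 0.5, and the proposed model adaptation —
  multiplying the panic decay rate by 10 — is asserted to strictly
  reduce it (0.68 → 0.07 under defaults). An alternative reading that
  dissolves the incongruence is to interpret the panic state as a
  *tendency* to panic rather than the momentary attack.
* **Solver cross-validation band.** The acceptance property "adaptive
  RK matches Euler (dt = 1e-4) within 1e-3 max-abs per component on
  every bundled scenario" holds on the exposure and cbt scenarios
  (7e-5) but not on baseline and reappraisal (2.3e-2 and 3.6e-3). The
  discrepancy is the *oracle's* first-order truncation error: through
  the quasi-exponential avoidance build-up (to ≈ 8 intensity units by
  mid-horizon), halving the Euler step halves the gap, while
  tightening the adaptive tolerance from 1e-8 to 1e-10 moves the RK
  solution by only 1.4e-4. An absolute 1e-3 band on such a component
  would need dt ≈ 5e-7. The corresponding acceptance test asserts the
  stated band verbatim and is expected to fail there; re-tuning the
  model toward a numerics criterion would calibrate against the wrong
  target.
* **Scope.** Linear-plus-bilinear dynamics only (no chaotic regimes),
  no stochastic terms, no delay equations, no estimation from
  empirical time series, no social/contextual coupling between
  individuals. These are future-work directions of the underlying
  framework, not accidental omissions.

## Reproducing the scenario suites

```{r scenarios, eval = FALSE}
for (name in c("baseline", "exposure", "reappraisal", "cbt")) {
  sc <- make_scenario(name)
  traj <- simulate_system(sc$spec, sc$plan)
  checks <- run_checks(extract_features(traj, sc$plan), name)
  cat(name, ":", all(vapply(checks, `[[`, TRUE, "passed")), "\n")
}
```
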