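# facsim

**Formalized functional-analysis case conceptualizations as dynamical
systems.**

`facsim` is an R package for clinicians and computational-psychiatry
researchers who want to turn an *idiographic* case conceptualization —
a functional analysis (SORKC model) of one individual patient — into a
simulable system of coupled ordinary differential equations, test
formalized interventions on it *in silico*, and check whether the
theory-implied trajectories reproduce the clinical phenomena the theory
is supposed to explain.

## The model at its core

The bundled reference system formalizes the functional analysis of a
hypothetical panic-disorder patient. A discriminant stimulus *S<sup>d</sup>*
(heart racing) drives catastrophic interpretation *R<sup>c</sup>* ("I am
having a heart attack"), which drives panic *R<sup>e</sup>*; the patient
copes through avoidance *R<sup>b</sup>* (leaving the situation). Panic and
avoidance are coupled like prey and predator, in the Lotka–Volterra
sense: panic feeds the growth of avoidance, avoidance suppresses panic.
Avoidance is reinforced by its perceived benefits *B* (relief) and
inhibited by its accumulating perceived costs *C* (withdrawal, work
problems); persistent avoidance removes opportunities to falsify the
catastrophic interpretation, so its credibility *γ<sub>cat</sub>* ∈ [0, 1]
grows and amplifies catastrophizing:

```
dRc/dt = a_c · Sd · (1 + g_cred · γ_cat) − d_c · Rc           [− a_inh · γ_fun · Sd]
dRe/dt = a_e · Rc − r · Re · Rb − d_e · Re
dRb/dt = a_b · Re · Rb · max(0, 1 + g_B · B − g_C · C) − d_b · Rb
dB/dt  = a_B · Re · Rb − d_B · B
dC/dt  = a_C · Rb − d_C · C
dγ_cat/dt = a_γ · Rb − d_γ · γ_cat                            [− k · γ_fun]
dγ_fun/dt = a_f · u(t) − d_f · γ_fun                          [augmented variant]
```

Two CBT interventions are formalized: **exposure** clamps avoidant
coping to 0 from its onset (confrontation with response prevention),
and **cognitive reappraisal** adds a competing *functional*
interpretation of the stimulus ("too much coffee") whose credibility
*γ<sub>fun</sub>* is built up by therapeutic input *u(t)*, inhibits
catastrophizing, and competes with the catastrophic credibility. The
`cbt` scenario applies both at once. Parameters are deliberately
treated as idiographic "tuning knobs"; the bundled defaults were
obtained by the package's own qualitative calibration procedure
(`calibrate_by_phenomena()`), documented in the methods vignette.

## Worked example

```r
library(facsim)

sc     <- make_scenario("exposure")          # bundled scenario 2
traj   <- simulate_system(sc$spec, sc$plan)  # adaptive RK, t_max = 50
report <- extract_features(traj, sc$plan)
report[report$component %in% c("Re", "Rb", "benefits"),
       c("component", "peak_value", "pre_onset_value",
         "short_term_max", "final_value")]
#>   component peak_value pre_onset_value short_term_max final_value
#> 2        Re      2.153           2.097          2.153    3.80e-01
#> 3        Rb      0.602           0.602          0.000    0.00e+00
#> 4  benefits      0.605           0.587          0.605    7.14e-05

for (ck in run_checks(report, "exposure")) print(ck)
#> [PASS] s2a: short-term panic spike after onset
#> [PASS] s2b: long-term panic decays under intervention
#> [PASS] s2c: perceived benefits of avoidance disappear
#> [PASS] s2d: catastrophizing and catastrophic credibility end up decreasing
```

Reading: once avoidance is clamped at the onset (t = 12.5), panic
briefly rises (its avoidance-mediated relief pathway is gone), then
decays to 18% of its pre-onset level because confrontation erodes the
credibility of the catastrophic interpretation; the perceived benefits
of avoiding collapse to effectively zero.

The model's acknowledged limitation — simulated panic *persists* in the
long term without intervention instead of spiking and subsiding like a
real panic attack — is itself a regression check, together with the
proposed adaptation (stronger panic decay):

```r
base <- extract_features(simulate_system(make_scenario("baseline")$spec))
print(known_incongruence_check(base)$measured)
#> ratio_default ratio_strong_decay
#>         0.677              0.072
```

Plots: `plot_timeseries(traj)` and `plot_phase_portrait(traj)` (3D
trajectory of panic × avoidance × catastrophic credibility, white
square = start, black square = end).

## Command line

```sh
Rscript -e 'quit(status = facsim::cli_main())' run --scenario cbt --out results --plot --checks
Rscript -e 'quit(status = facsim::cli_main())' validate --config my_system.json
Rscript -e 'quit(status = facsim::cli_main())' calibrate --ranges ranges.json --budget 500 --seed 1
```

`run` exits 0 only if the simulation succeeded and (with `--checks`)
every scenario check passed; configuration/spec errors exit 2. Bundled
scenario configs live in `inst/extdata/` (`scenario1.json`,
`exposure.json`, `reappraisal.json`, `cbt.json`).

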