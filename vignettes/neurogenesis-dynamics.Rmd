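---
title: "Modelling adult hippocampal neurogenesis with neurodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adult hippocampal neurogenesis with neurodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

## The model and its assumptions

`neurodyn` describes adult hippocampal neurogenesis as a linear system of
five ordinary differential equations for the counts of neural stem cells
(`c1`), progenitors (`c2`), neuroblasts (`c3`), mature neurons (`c4`) and
astrocytes (`c5`). The system is the mean-field limit of an explicit
cell-level event model: every cell waits an exponential time for its next
event, and the event outcome is drawn from the division diagram encoded in
`ng_params()`. Three assumptions shape everything downstream:

* **Linearity.** No feedback or saturation terms: every rate is
  proportional to a compartment count. This is deliberate — the package
  targets *short-term* responses to a knockout (KO), for which no
  regulatory feedback is established, and linearity is what makes the
  closed-form solutions and the exact sensitivity analysis possible.
* **Exponential lifetimes.** Event waiting times are exponential, the
  standard branching-process idealisation. Real cell-cycle times are not
  exponential; consequences are discussed under *Limitations*.
* **Stem cells do not die.** The only stem-cell loss channel is direct
  astrocytic transformation, so the net stem rate
  `lambda1 = (2*a1*theta1 - 1)*p1` already contains all losses. All other
  compartments carry explicit death rates.

The stem pool is autonomous, `c1(t) = n1 * exp(lambda1 * t)`, and declines
monotonically exactly when `a1 * theta1 <= 1/2`: depletion happens when
symmetric self-renewing divisions are rarer than astrocytic
transformations. We treat the equality case as the balanced boundary
(constant stem pool) and report it separately (`check_stem_decline()`).
The progenitor equation is a driven linear cascade with the explicit
solution implemented in `closed_form_c2()`; when `lambda1 == lambda2` the
generic formula degenerates and the secular limit
`(n2 + k12*n1*t) * exp(lambda*t)` is used instead of raising an error
(triggered below `~1e-12` relative rate separation, where the generic
expression loses precision).

The analytic sign results below additionally assume the *declining-niche
regime* (`check_assumption()`): stem pool declining, and progenitors
depleting strictly faster (`lambda2 < lambda1`). The reference parameter
set shipped as the `ng_params()` defaults sits in this regime.

Time is measured in abstract "model time units" throughout: the reference
parameter set is a regime choice, not a physiological calibration, so no
time unit is attached to it.

### Parameters

| parameter | meaning | default | range |
|---|---|---|---|
| `a1`, `a2` | fraction of self-renewal (probability a daughter keeps its mother's fate); `2a - 1` is the symmetric-division probability | 0.55, 0.7 | `[1/2, 1]` |
| `theta1`, `theta2` | probability the next event is a division, not a transformation | 0.7, 0.4 | `[0, 1]` |
| `p1`, `p2` | proliferation rate: per-cell event rate, per model time unit | 1, 2.5 | `> 0` |
| `kappa` | probability the non-stem daughter of an asymmetric stem division is a progenitor (else astrocyte) | 0.6 | `[0, 1]` |
| `p3` | neuroblast maturation rate | 1.5 | `> 0` |
| `d2`..`d5` | death rates of progenitors, neuroblasts, neurons, astrocytes | 0.1, 0.4, 0.05, 0.05 | `>= 0` |

Counting conventions: the kinetic model has 12 parameters, plus 5 initial
counts, i.e. 17 quantities; descriptions of this model family sometimes
quote 18, and the most plausible 18th is the BrdU exposure duration
`delta`, which we treat as part of the labelling protocol rather than the
model. We document the discrepancy rather than guess.

## The BrdU labelling submodel

BrdU marks cells that synthesise DNA — i.e. divide — while the marker is
present. A pulse-chase experiment is described by `labeling_protocol()`:
injection at `t_hat` after the KO, exposure `delta`, readout `tau` after
the window ends. `delta` defaults to 0.1 model time units; it is a
protocol input everywhere, never a differentiated parameter.

The labelled pools at the end of the window are built from the
division-fraction construction (`initial_labels()`): a fraction
`1 - exp(-p_i*delta)` of cells present at injection undergoes an event
during the window, `theta_i` of those divide, and each division
contributes on average `2*a_i` same-fate and `2*(1-a_i)` other-fate
labelled daughters. Transformations synthesise no DNA and never label, so
there are no labelled neurons at `tau = 0`. During the chase, labelled
cells obey the *same* linear dynamics as their compartments
(`labeled_trajectory()`): all progeny of a labelled cell count as
labelled, BrdU dilution over generations is ignored.

This construction is first-order in `delta`. It neglects (i) repeat
divisions of one lineage inside the window, (ii) the drift of the
population during the window, and (iii) migration of freshly labelled
cells to the next compartment before the window closes. (iii) is worth
understanding: it is second order in absolute size but *first order
relative to small pools*, so at `delta = 0.05` the labelled-neuroblast
pool is underestimated by roughly 14% while the much larger stem pool is
accurate to under 1%, and a handful of labelled neurons exist at `tau = 0`
even though the formula says zero. The package quantifies this exactly:
`window_label_mean()` integrates the within-window master equation
`dL/dt = A L + B (c - L)` (with `B` the labelled-daughter creation matrix)
and is the exact expectation of the stochastic simulator at `tau = 0`.

```{r window-error}
p <- ng_params()
s <- ng_state()
rbind(formula = unlist(initial_labels(p, s, 0.05)),
      exact   = unlist(window_label_mean(p, s, 0.05)))
```

The total labelled count is insensitive to the migration terms (they only
move labels between pools), which is why formula and simulator agree on
the total to well under 2% at `delta = 0.05` while individual small pools
disagree by more.

## Sensitivity analysis of knockout responses

An inducible stem-cell KO is modelled as an instantaneous change of `a1`,
`p1` or `theta1` at `t = 0`. For infinitesimal changes the response is the
parameter derivative of the solution, computed by the forward-sensitivity
system `s' = A s + (dA/dp) c`, `s(0) = 0` (`sensitivity()`). For this
linear constant-coefficient model the augmented system is itself linear
and constant, so the approach is exact up to integrator tolerance — no
symbolic differentiation is needed. Three independent routes guard the
implementation: hand-derived closed forms for the stem and progenitor
derivatives (`analytic_sensitivity()`, agreement demanded at 1e-6
relative), central finite differences (`fd_sensitivity()`, 1e-4
relative), and finite-perturbation KO runs (`ko_response()`, first-order
Taylor agreement).

Derivatives of BrdU-incorporating pools chain the labelling matrix into
the count sensitivities; because that matrix depends on the stem
parameters directly, labelled responses are generally non-zero already at
`t = 0` — labelling "sees" a parameter change faster than the raw counts
do. Derivatives through a full pulse-chase experiment
(`label_sensitivity()`) propagate through three stages: pre-labelling
trajectory, window pools, chase dynamics.

Responses are summarised as *sign sequences* (`sign_sequence()`): the
ordered distinct signs a curve traverses, e.g. `(0, -, 0, +)` for a
response that starts at zero, dips, and recovers. Numerical choices, all
configurable:

* grid: 3001 points on `[0, 30]` model time units. The horizon exceeds
  the slowest system timescale (`1/d4 = 20`) so no phase is truncated;
* zero tolerance: `1e-6` of the curve's maximum absolute value — values
  below it count as zero, which both absorbs integrator noise and renders
  the exact leading zeros;
* an isolated crossing between two grid points is recorded as a `0`
  symbol at the linearly interpolated root. The times of entry into and
  exit from such a zero coincide, so crossing times are non-decreasing
  with ties at isolated crossings rather than strictly increasing;
* `phase_count()` counts maximal nonzero runs: `(0, -, 0, +)` is a
  two-phase response.

In the declining-niche regime the full classification (`ko_sign_table()`)
is: raising `a1` helps stem cells immediately but progenitors and
labelled astrocytes only after an initial deficit; raising `p1` trades a
transient labelled surplus for long-run depletion; raising `theta1` helps
everything. Outside the regime the table is still produced, with a
warning. Two numerical facts about the time structure are worth noting,
since both are slower than intuition suggests: with `d4 = 0` the neuron
response to `a1` approaches its positive plateau on the `1/|lambda1|`
(about 4.3 time units) timescale and still changes by a few percent
between `t = 25` and `t = 30`; with `d4 = 0.05` the response decays after
its peak at rate `d4`, so it is still at about 70% of its maximum at
`t = 30` and reaches 10% only around `t = 65`.

```{r neuron-tail}
tt <- seq(0, 30, length.out = 3001)
s4 <- sensitivity(ng_params(d4 = 0), s, "a1", tt)$c4
tail4 <- s4[tt >= 25]
c(rel_change_25_30 = (max(tail4) - min(tail4)) / mean(tail4))
s4d <- sensitivity(p, s, "a1", tt)$c4
c(value30_over_max = s4d[length(tt)] / max(s4d))
```

The astrocyte *count* response (`c5`) is computed numerically but no
analytic sign claim is made for it: its classification depends on a
coefficient combination whose sign is not determined in general.

## Fitting age-decline data

`fit_age_series()` fits the closed-form stem/progenitor curves to
per-age means with standard errors, minimising the residual sum weighted
by inverse squared s.e.m. From stem and progenitor counts alone, only the
composites `lambda1`, `lambda2`, `K = k12*n1`, `n1`, `n2` are
identifiable — the individual probabilities and rates enter only through
them — so the optimiser works on `(lambda1, lambda2, log K, log n1,
log n2)`, positivity enforced by the log transform. Optimisation is
multi-start (default 100 starts): a data-driven centre from log-linear
regression of each compartment, random perturbations around it, each
polished by Nelder-Mead (restarted when the iteration budget is hit), and
determinism guaranteed by the seed. Two modes mirror the two natural
observation sets: `c1_c2` (stem and progenitor counts) and `c1_ratio`
(stem counts and the stem/progenitor ratio; ratio standard errors are
taken from the data when present, otherwise propagated to first order —
the choice is documented because it affects weights, not the argmin).
`r.squared` is computed on the weighted residuals, matching the
objective; with replicate-estimated standard errors the standardised
residuals are t-distributed (3 degrees of freedom at 4 replicates), so
the weighted SSR at the truth is about 3 per observation, not 1.

A caution the worked examples make explicit: with 5% noise the slow rate
`lambda1` and the initial counts are recovered to about 1%, but
`lambda2` and `K` are informed only by the earliest ages (the fast
transient) and can wander far with little SSR penalty. The synthetic
saturation fixture (below) reproduces the qualitative failure mode of
exponential stem decline against a late-age floor: fitted to stem counts
and the ratio, the model misdescribes progenitors, and vice versa.

## The stochastic oracle

`simulate_population()` and `simulate_brdu()` run an exact event-driven
(Gillespie) simulation of the cell-level rules, implemented in C++.
Because all rates are linear, population-level propensities are
distributionally exact — no per-cell agents are needed. Competing risks
(e.g. progenitor event vs death) are independent exponential clocks,
matching the additive ODE terms. During the exposure window every
completing division marks both daughters; labels are heritable;
transformations never create a label. Randomness comes from R's own RNG
stream, so `set.seed()` / the `seed` arguments give identical event
sequences across runs; an event cap (default 1e7) aborts runaway
populations explicitly. Ensemble means converge to the ODE solutions at
the usual `1/sqrt(n_rep)` rate; the tests verify this, the martingale
property of the balanced stem pool, and the exact window master equation
per compartment at three Monte-Carlo standard errors.

## Synthetic data

`generate_age_series()` emulates a stereological counting study: at each
age, `replicates` animals are drawn as multiplicative lognormal
(mean-preserving) noise around the closed-form curves; the reported mean
is the replicate average, the s.e.m. is the replicate SD over
`sqrt(replicates)`. Defaults — 10 ages on `[0, 24]` model time units
(evoking months of adult age), cv 5%, 4 replicates — are plausible for
such studies. An optional `saturation_floor` (e.g. 320 cells) pins the
true late-age stem counts above the exponential curve, emulating a
residual quiescent pool. `generate_ko_dataset()` produces paired
wild-type/KO observations of counts and labelled counts.

What the generator deliberately does *not* emulate: correlated counting
errors across compartments of one animal, age-dependent noise beyond the
multiplicative model, systematic stereological bias, and any real
saturation mechanism (the floor is a phenomenological distortion).
Passing the recovery and misfit tests therefore shows that the estimation
machinery is correct and that the misfit diagnostic works — not that the
exponential model describes real age-decline data, which in fact it
demonstrably fails to do at late ages.

## Scenario runner

`load_scenario_config()` / `run_scenario()` tie the stages into
reproducible runs driven by a JSON/YAML config (unknown keys rejected,
invalid values named; a reference config ships in
`inst/extdata/reference_scenario.json`). Every run writes its artifacts
as CSV/JSON plus a log with package version, seed and solver settings;
reruns are byte-identical. A thin command-line wrapper lives at
`inst/scripts/neurodyn-run.R`; the R functions are the primary
interface.

## Numerical choices, at a glance

* integrator: `deSolve::lsoda` with analytic Jacobian, `rtol 1e-10`,
  `atol 1e-12`; trajectory round-off below `~1e-8` cells clamped to zero;
* closed-form vs numeric agreement required at 1e-8 relative in tests;
* sensitivity cross-checks: analytic 1e-6, central differences 1e-4
  (step `1e-6 * max(1, |p|)`, domain-checked);
* sign detection: 3001-point grid on `[0, 30]`, zero tolerance 1e-6
  relative, interpolated roots for isolated crossings;
* fitting: Nelder-Mead, `reltol 1e-14`, up to 10000 iterations with up to
  three restarts, 100 starts by default;
* tests run the stochastic oracle at 200-400 replicates with the
  reference initial counts (1e4 stem cells) over horizon 5, and the
  recovery study at 50 datasets of 10 ages — sizes chosen so each check
  has clear statistical power.

## Limitations

* No feedback, quiescence or saturation: the model is built for
  short-term KO responses, and its exponential stem decline is known to
  underestimate late-age stem counts (the saturation fixture exists
  precisely to exhibit this).
* Exponential lifetimes: cell-cycle structure (e.g. a minimum S-phase
  duration) is not represented; the fraction of dividing cells is taken
  to equal the fraction of DNA-synthesising cells during any window.
* The fraction-based labelling formula carries the first-order-in-delta
  migration error quantified above; for `delta` beyond ~0.1 the exact
  window mean should be preferred.
* Sensitivity-based KO interpretation is local: finite parameter jumps
  of KO size are better served by `ko_response()`, which the tests tie to
  the derivatives at small perturbations.
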