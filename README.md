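# neurodyn

Compartmental dynamics of adult hippocampal neurogenesis in R.

In the adult dentate gyrus, neural stem cells generate neurons through a
hierarchy of intermediate stages, and the whole cascade runs down with age.
Inducible knockout (KO) experiments perturb stem-cell behaviour and read the
consequences off cell counts and BrdU-labelled cell counts — but those
readouts respond in time-dependent, multi-phase, sometimes counter-intuitive
ways. `neurodyn` implements a linear five-compartment model of this system
for people who want to interpret such experiments quantitatively:
modellers analysing KO readouts, and experimentalists deciding *when* to
count which cells.

## The model

Five compartments — stem cells (c1), progenitors (c2), neuroblasts (c3),
neurons (c4), astrocytes (c5) — evolve by

    c1' = lambda1 * c1
    c2' = k12 * c1 + lambda2 * c2
    c3' = k23 * c2 - (p3 + d3) * c3
    c4' = p3 * c3 - d4 * c4
    c5' = k15 * c1 - d5 * c5

where the coefficients collapse an explicit division bookkeeping: a stem
cell undergoes events at proliferation rate `p1`; each event is a division
with probability `theta1` (else a direct astrocytic transformation), a
division is symmetric with probability `2*a1 - 1` (two stem daughters) and
asymmetric otherwise, and the non-stem daughter of an asymmetric division
is a progenitor with probability `kappa` or an astrocyte otherwise.
Progenitors behave analogously (`a2`, `theta2`, `p2`, death `d2`), feeding
neuroblasts, which mature into neurons at rate `p3`. Hence

    lambda1 = (2*a1*theta1 - 1) * p1        net stem-cell rate
    lambda2 = (2*a2*theta2 - 1) * p2 - d2   net progenitor rate
    k12     = 2*(1-a1)*theta1*kappa*p1      stem -> progenitor flux
    k23     = (2*(1-a2)*theta2 + 1-theta2) * p2
    k15     = ((1-theta1) + 2*(1-a1)*theta1*(1-kappa)) * p1

The stem pool declines if and only if `a1*theta1 <= 1/2`. On top of the
counts, the package models BrdU pulse-chase labelling (division-fraction
initial pools, identical linear chase dynamics), forward parameter
sensitivities with sign-sequence classification of KO responses, weighted
least-squares fitting of age-decline data, an exact Gillespie simulator of
the underlying branching process, and a seeded synthetic-data generator.
All user-facing functions take and return tibbles and compose with the
pipe; fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(neurodyn)

pars <- ng_params()        # reference set; ng_params(a1 = ..., ...) to change
traj <- ng_solve(pars, ng_state(), times = seq(0, 10, by = 2))
traj
#>    time     c1    c2     c3      c4      c5
#> 1     0 10000  5000  15000  350000  100000
#> 2     2  6313. 2560.  3546. 336237.  98873.
#> 3     4  3985. 1562.  1983. 311719.  94760.
#> 4     6  2516.  981.  1235. 286538.  89085.
#> 5     8  1588.  619.   778. 262083.  82718.
#> 6    10  1003.  391.   491. 238917.  76179.
```

The stem pool decays exponentially (`lambda1 = -0.23` per model time unit),
progenitors track it after a fast transient, and the ratio c1/c2 settles at
`(lambda1 - lambda2)/k12 = 2.57`.

How would cell counts respond to a KO that changes one stem-cell
parameter? `ko_sign_table()` classifies the response of each observable as
the ordered signs it passes through (a leading 0 means the response starts
at zero; `l*_plus` are BrdU-incorporating pools):

```r
ko_sign_table(pars, ng_state()) |>
  dplyr::select(parameter, quantity, signs) |>
  tidyr::pivot_wider(names_from = quantity, values_from = signs)
#>   parameter c1     l1_plus   c2           l2_plus   l5_plus
#> 1 a1        (0, +) (+)       (0, -, 0, +) (-, 0, +) (-, 0, +)
#> 2 p1        (0, -) (+, 0, -) (0, +, 0, -) (+, 0, -) (+, 0, -)
#> 3 theta1    (0, +) (+)       (0, +)       (+)       (+)
```

Read the first row: raising the fraction of self-renewal `a1` increases
stem counts at every later time, but progenitors first *drop* (fewer
asymmetric divisions) before the enlarged stem pool makes them rise — a
two-phase response. Labelled pools react instantly (no leading zero),
because BrdU marks exactly the division output the parameter changed.

Fitting a noisy synthetic age series recovers the identifiable composites:

```r
d <- generate_age_series(age_series_design(cv = 0.05, seed = 42))
fit <- fit_age_series(d, mode = "c1_c2", n_starts = 20, seed = 1)
tidy(fit)
#>   term     estimate
#> 1 lambda1    -0.231     (true -0.23)
#> 2 lambda2    -6.30      (weakly identified at this noise level)
#> 3 K       24324.
#> 4 n1      10213.        (true 10000)
#> 5 n2       4988.        (true 5000)
glance(fit)
#>     ssr r.squared mode  n_starts converged
#> 1  15.8     0.999 c1_c2       20 TRUE
```

The slow rate `lambda1` and the initial counts are recovered to about 1%;
the fast progenitor transient (`lambda2`, `K`) is only informed by the
earliest ages and is weakly identified from 5%-noise data — exactly the
kind of diagnosis the package is meant to support. `autoplot(fit)`,
`autoplot(traj)` and `autoplot(sensitivity(...))` draw the standard
figures.

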