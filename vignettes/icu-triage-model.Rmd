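---
title: "Modelling ICU triage policies: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ICU triage policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icutriage)
```

## The question

When intensive-care demand exceeds capacity, some rule must decide who
receives a bed. Two families of rules are debated: *ex-ante* triage, which
ranks only newly presenting patients by prognosis when filling free beds,
and *ex-post* triage, which additionally lets currently treated patients
compete with the queue, so that an allocated bed can be withdrawn in favour
of a patient with better survival odds. German law permits the former and
forbids the latter; the quantitative cost of that prohibition — in total
mortality and in the mortality of patients with disabilities or
pre-existing conditions — is what this simulator measures.

## The model

An ICU with `B` beds is simulated over a short horizon. At initialisation
(`t = 0`) a demand of `d` patients competes for the `B` beds; at each of
`T` consecutive time points a fresh queue of `w` patients arrives and a
reallocation step is performed. Six policies cross the initial mode
(random; ex-ante by prognosis; 90% random / 10% ex-ante) with the
consecutive mode (random replacement of 10% of capacity; ex-post triage of
the pooled cohort and queue).

Each patient `i` carries:

* `x_i ∈ {0, 1}` — whether the patient has one of the modelled
  comorbidities (probability `s`);
* a condition `k` for comorbid patients — a disability with probability
  0.10, otherwise a pre-existing disease, the concrete condition drawn by
  within-category prevalence weights;
* a true death probability `p_i ~ Δ(a_k, b_k, c_k)`, a triangular
  distribution depending on the condition;
* a death indicator `y_i ~ Bernoulli(p_i)`, drawn once at generation.

The reported outcome is the *prospective mortality* of the treated cohort,

```
m_t = (1/B) · Σ_{i treated at t} y_i ,
```

together with the group-specific versions `m_t^n` (no comorbidity) and
`m_t^v` (comorbid), and per-group counts of treated, admitted and
discharged patients. `m_t` is a forward-looking property of the cohort:
patients who would die are not removed from their beds, because the model
deliberately excludes natural patient flow to isolate the allocation
effect.

### Death-probability distributions

The baseline distribution for patients without comorbidities is
`Δ(0.04, 0.41, 0.045)` (minimum, maximum, mode) with mean
`E(X) = 0.165`. Comorbidity-specific distributions are derived by scaling
this mean with a literature-based relative death risk (odds or hazard
ratios, treated uniformly as multiplicative risks):

| condition | ratio | derived mean |
|---|---|---|
| trisomy 21 | 4.52 | 0.746 |
| amyotrophic lateral sclerosis | 3.00 | 0.495 |
| cardiovascular disease | 4.85 | 0.800 |
| hypertension | 2.12 | 0.350 |
| type-2 diabetes | 2.03 | 0.335 |

Only the hypertension triangle is fixed explicitly, at
`Δ(0.19, 0.63, 0.23)` (mean 0.35). For the other four conditions the
construction rule is a design choice of this package: we *translate* all
three vertices by `0.165 · (ratio − 1)`, which preserves the shape of the
baseline distribution and scales the mean exactly. Translation is the
simplest mean-correct rule, and the explicit hypertension mode (0.23) is
consistent with it (translation predicts 0.2298). The explicit hypertension
minimum and maximum are some 0.035 wider on each side than translation
predicts; a `translate_widen` method is therefore available, which widens
the support symmetrically by a configurable amount (mean unchanged,
default 0: we do not extrapolate one condition's widening to the others).
When translation pushes the support outside `[0, 1]` — cardiovascular
disease, mean 0.80, translated maximum 1.045 — the offending endpoint is
clamped and the remaining vertices shifted equally so the target mean is
preserved exactly; infeasible targets (mean > 1) raise an error instead of
silently distorting the risk.

Overlap between densities quantifies how much prognosis-based triage *can*
discriminate between groups. `overlap_fraction()` integrates the pointwise
minimum of the two densities exactly, by collecting every vertex and every
crossing point of the two piecewise-linear densities and summing exact
trapezoids — deterministic and testable, unlike Monte-Carlo integration.
For the baseline/hypertension pair the exact integral is 31.71%, against a
published figure of 31.35% whose computation method is unstated; the
residual 0.36 percentage points is within the tolerance we accept for this
quantity and is flagged here rather than hidden.

### Prevalence weights and calibration

The one input not fully published is the per-condition prevalence weights
of the mixed scenario. Our defaults are motivated by approximate German
prevalences (within-category proportions are all that matters): trisomy 21
≈ 50,000 and ALS ≈ 9,000 people for the disability category; 7 / 30 / 9
(percent of adults) for cardiovascular disease / hypertension / type-2
diabetes. These raw weights give a comorbid mixture mean of 0.445.
`calibrate_prevalence_weights()` then applies a one-parameter exponential
tilt `w_k → w_k · exp(λ · mean_k)` — the smallest smooth adjustment that
can move the mixture mean — with `λ` solved so the mixture mean equals
0.438, the comorbid-group mortality observed under the fully random
policy, which estimates exactly that mean because random allocation never
selects on prognosis. This calibration is applied once, in
`default_mix()`, and is an anchor, not a fitted result: it fixes the level
of comorbid risk, while everything the experiments compare (differences
between policies, group disparities, trajectories) is left free.

### Misestimation

Clinicians see `p'_i = e · p_i`, not `p_i`. Because every allocation rule
ranks patients, and ranking is invariant to multiplication by a positive
scalar, `e` provably cannot change any allocation — the package reproduces
this *exactly* (identical random streams, identical outputs for any `e`),
not merely statistically. Uniform misestimation is of course the least
harmful kind; patient-specific errors would break the invariance and are
outside this model's scope.

## Randomness and reproducibility

A single `master_seed` drives everything. Per replication, named
substreams are derived by an integer mixing function (exact in double
arithmetic, platform-independent): one for the initial demand, one for the
initial allocation, and one per time point for the queue and the step.
Policy id and `e` are deliberately excluded from the derivation, so

* policies sharing an initial mode (pairs 0/1, 2/3, 4/5) see bitwise
  identical initial cohorts — their `t = 0` results are equal by
  construction, as they should be;
* runs differing only in `e` see identical draws throughout.

Each generated patient consumes exactly five uniforms in a fixed order
(comorbidity, category, condition, probability, indicator), whether or not
all five are needed, so generation is invariant to batch size. Triangular
draws are inverse-transform (one uniform each). Tie-breaks in triage
ranking use a uniform key drawn unconditionally from the step's stream:
ties have probability zero for continuous `p`, but the contract must be
total, and drawing the key unconditionally keeps stream alignment
independent of the data.

## Numerical and degenerate-input choices

* Group mortality uses the group's *treated count* as denominator;
  replications in which a group is absent from the cohort contribute no
  value and are counted (`n_*_absent` in the summary). On this scale the
  healthy group's mortality under random allocation equals the baseline
  mean 0.165, which is the consistency check the summary tables must pass.
* Degenerate triangles (point masses) are valid inputs: sampling returns
  the atom, overlap is 1 for identical atoms and 0 otherwise.
* Random replacement turns over `floor(0.1 · B)` beds regardless of queue
  length, which is how the replacement intensity stays fixed while the
  queue length is varied in sensitivity runs.
* Policies with purely random initial allocation generate exactly `B`
  patients (demand plays no role when no selection happens); a
  `random_init_from_pool` switch generates `d` and samples `B` of them
  instead.
* ANOVA on a degenerate (zero-variance) input reports `F = NA, p = NA`
  with a flag instead of crashing.

## Study conditions and problem sizes

The default configuration — `R = 10,000` replications, `B = 60`, `d = 70`,
`w = 10`, `s = 0.7`, `T = 3`, `e = 1`, six policies — is the mixed-population
scenario at full scale; a complete run takes on the order of two to three
minutes on one core. Unit and property tests run the same engine at
reduced replication counts (tens to hundreds), which is ample for
structural properties (conservation laws, invariances, orderings) while
the full-scale tolerance checks use `R = 10,000`.

## What the generator does and does not emulate

The generator reproduces the study conditions: a stationary overload, a
fixed comorbid share, conditions assigned by prevalence within two
categories, static per-patient prognosis. It does **not** model arrival
dynamics, length-of-stay, recovery or deterioration during treatment
(scores changing over time), re-presentation of denied patients
(patients denied or discharged are assumed to die), correlations between
comorbidity and age or between multiple conditions, or uncertainty in the
published risk ratios (their confidence intervals are recorded in the
documentation but only the point ratios are used). Passing tests
therefore validate the allocation logic and the distributional machinery
under these idealised conditions; they do not validate transfer to a real
ICU, where dynamic prognosis updating in particular could change the
ex-post ranking substantially.

## Known limitations

* The four unprinted comorbidity triangles make the comorbid
  *distribution shape* (not its mean, which is calibrated) a modelling
  choice; tail-sensitive quantities — most visibly how much death
  probability the ex-post step removes — inherit that uncertainty.
* The calibration anchor ties the mixture mean to one published group
  mortality; alternative anchors (e.g. total mortality) would shift
  levels slightly but not policy orderings.
* Uniform misestimation only; the exact `e`-invariance is a property of
  scalar scaling, not a claim about heterogeneous clinical error.

## A minimal session

```{r, eval = FALSE}
cfg <- experiment_config(replications = 10000, master_seed = 1)
ex <- run_experiment(cfg)
print(ex)                       # mean total mortality by policy and time
mortality_table(ex, time = 1)   # per-group table at the first reallocation
compare_policies(ex, time = 1)  # ANOVA + Tukey over replication values
```
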