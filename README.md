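# icutriage

Patient-level Monte-Carlo simulation of intensive-care bed rationing under
surge conditions, built to quantify a policy question: what does it cost,
in ICU mortality, to forbid **ex-post triage** — the reallocation of an
already occupied bed to a patient with better survival odds — while
allowing only **ex-ante triage** of free beds? The comparison pays
particular attention to patients with disabilities and pre-existing
conditions, the group the prohibition is meant to protect.

## Model in brief

An ICU with `B = 60` beds faces an initial demand of `d = 70` patients and
a fresh queue of `w = 10` patients at each of `T = 3` reallocation time
points. Patient `i` has a comorbidity indicator `x_i` (`P(x_i = 1) = s =
0.7`), a true death probability `p_i ~ Δ(a_k, b_k, c_k)` — a triangular
distribution with condition-specific minimum, maximum and mode — and a
pre-drawn death indicator `y_i ~ Bernoulli(p_i)`. Patients without
comorbidity draw from `Δ(0.04, 0.41, 0.045)` (mean 0.165); comorbid
patients draw from triangles whose means are the baseline mean scaled by
literature-based relative death risks (e.g. hazard ratio 2.12 for
hypertension, giving `Δ(0.19, 0.63, 0.23)` with mean 0.35). Six policies
cross the initial allocation (random / ex-ante by lowest perceived death
probability `e·p_i` / 90% random + 10% ex-ante) with the consecutive step
(random replacement of 10% of capacity / ex-post triage of the pooled
cohort and queue). The outcome per time point is the prospective mortality
of the treated cohort,

    m_t = (1/B) · Σ_{i treated} y_i,

plus the per-group versions and treated/admitted/discharged counts,
averaged over `R = 10,000` replications, with one-way ANOVA and Tukey
post-hoc tests across policies as validation.

## Worked example

```r
library(icutriage)
cfg <- experiment_config(replications = 500, master_seed = 1)
ex <- run_experiment(cfg)
print(ex)
```

```
Triage simulation experiment: 6 policies x 500 replications, t = 0..3
B = 60 beds, d = 70, w = 10, s = 0.70, e = 1, seed = 1

Mean total mortality (%):
    policy0 policy1 policy2 policy3 policy4 policy5
t=0    35.6    35.6    28.7    28.7    34.0    34.0
t=1    35.6    28.8    29.4    25.5    34.1    27.5
t=2    35.8    25.7    30.2    23.8    34.4    24.7
t=3    35.5    23.5    30.5    22.0    34.2    22.6
```

Reading the table: policy 0 (random throughout) holds mortality at the
population average (~36%); policies with consecutive ex-post triage
(1, 3, 5) push it down further at every reallocation; ex-ante-only
policy 2 starts low but drifts back up once refilling is random. Per-group
values at the first reallocation:

```r
round(mortality_table(ex, time = 1), 1)
#>          policy0 policy1 policy2 policy3 policy4 policy5
#> all         35.6    28.8    29.4    25.5    34.1    27.5
#> healthy     16.3    16.2    16.2    16.2    15.8    15.8
#> comorbid    43.8    35.6    36.3    31.6    43.2    34.7
```

Healthy-group mortality stays near the baseline mean of 16.5% under every
policy; the mortality reduction from ex-post triage is concentrated in the
comorbid group (43.8% → 31.6% between policies 0 and 3) — although that
same group is also the one disproportionately discharged or denied, which
the admitted/discharged counts in `ex$summary` make explicit.
`compare_policies(ex, time = 1)` confirms the separation (one-way ANOVA,
F ≈ 218, p < 1e-190; at `t = 0`, pairs 0/1, 2/3 and 4/5 are identical by
construction and flagged non-significant).

Distribution diagnostics: `overlap_fraction()` computes the exact shared
area of two triangular densities, e.g. 31.7% for the baseline vs
hypertension pair — the overlap that keeps prognosis-based triage from
being a clean separator of the two groups.

A command-line wrapper with `run`, `grid`, `compare` and `overlap`
subcommands is installed at
`system.file("cli", "icutriage.R", package = "icutriage")`.

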