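---
title: "Methods: a lifetime Markov cohort model for ICD versus pharmacotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cohort model for ICD versus pharmacotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdcea)
```

## The model and its assumptions

The package implements a two-arm cohort state-transition model with
annual cycles. Patients treated with an implantable cardiac
defibrillator (ICD) move among five health states — well,
hospitalization, complication, device rejection, death — and patients on
anti-arrhythmic drugs among three (well, hospitalization, death). Death
is absorbing; the drug arm carries no mass into or out of the
complication and rejection states. Transition probabilities are
time-homogeneous: the same annual risks apply at every cycle, to first
hospitalizations and re-hospitalizations alike. Background all-cause
mortality is deliberately excluded — the death state reflects disease
progression and intervention-related complications only — so lifetime
projections are optimistic in the tail; this mirrors the source
analysis and several earlier ICD models.

Rewards: each live state accrues an annual cost (USD) and a utility
weight per cycle; death accrues nothing recurring but a one-time cost
(device explantation/terminal care in the ICD arm, $2,777; $467 in the
drug arm) applied to the fraction newly entering death that cycle,
discounted at the entry cycle. The rejection state has no published
cost or utility; it defaults to the arm's hospitalization values and
can be overridden in the parameter file (`cost_rej_icd`, `u_rej_icd`).

## Parameters that matter

| Setting | Default | Units | Why |
|---|---|---|---|
| `dr_cost` | 0.06 | /year | published cost discount rate (range 0.03–0.09) |
| `dr_outcome` | 0.03 | /year | published outcome discount rate |
| `wtp` | 13,002 | $/QALY | 3 × 2021 GDP per capita |
| `max_cycles` | 100 | cycles (years) | lifetime horizon; exceeds any survivable age from a mean age of 57 |
| `absorb_tol` | 1e-4 | fraction alive | stop once <0.01% of the cohort is alive |
| `half_cycle` | FALSE | — | the source analysis does not mention a half-cycle correction |
| `init_state` | WELL | — | see below |
| `psa_iterations` | 1000 | — | published Monte-Carlo iteration count |

The source abstract states a single 6% discount rate for both costs and
outcomes while the methods text discounts costs at 6% and outcomes at
3%; the methods values are the defaults and the inconsistency is noted
here rather than resolved.

**Discounting convention.** Cycle-`t` rewards are divided by
`(1+r)^t` with `t` starting at 0, so the first cycle is undiscounted.
Only the rates are published; this is the simplest convention and the
tests pin it via geometric-series closed forms.

**Initial state.** The cohort starts in *well*. The natural alternative
— starting in *hospitalization*, since the study population was
hospitalized patients — was examined and rejected on evidence: with a
well start the drug arm's published lifetime pair ($8,592, 11.29 QALYs)
is reproduced by calibration to better than 0.1%, while under a
hospitalization start no admissible parameter setting comes closer than
about 3.6% on cost. The published outputs therefore encode a model whose
cohort enters post-treatment in the well state. The choice is a setting
(`init_state`) and can be flipped.

## Distributions and sampling

Uncertain probabilities and utilities are beta, costs gamma, both
fitted from the published (mean, SD) by the method of moments
(`beta_from_moments()`, `gamma_from_moments()`); the fit is exact to
machine precision and rows without an SD are treated as fixed. In the
probabilistic sensitivity analysis each distribution-tagged parameter
is drawn independently — no covariance information is published — and
exit rows are renormalised: the sampled probability is kept, the
smallest-mean sibling (e.g. complication→rejection, 0.022) stays at its
base value, and the largest-mean sibling (the recovery probability)
absorbs the residual, clamped at zero. Clamp events are counted and a
warning is raised if more than 1% of PSA iterations clamp; at the
default inputs clamping is essentially never triggered.

Hospitalization→well is modelled as the exact complement of
hospitalization→death (the published table gives an SD only for the
death probability), so sampling the one determines the other.

**Seeding.** The PSA derives one integer substream seed per iteration
from the root seed, so runs are bit-reproducible and extending the
iteration count never changes earlier iterations.

## Deterministic sensitivity analysis

One-way bounds are mean ± 1.96·SD clamped to the parameter's domain;
parameters without an SD (including the calibrated well-exit
probabilities, which have no published uncertainty but whose leverage
should be visible) vary ±25%; the discount rates vary over the
published 0.03–0.09 range. The tornado sorts parameters by the width of
the ICER swing, ties broken lexicographically. The two-way analysis
defaults to the published well-state cost ranges (ICD $563–$9,096,
drug $42–$9,195) and records the strategy with the higher net monetary
benefit in each lattice cell. The CEAC grid spans $0–$50,000/QALY in
$500 steps, bracketing both the threshold and the base-case ICER.

## Calibration of the well-state exit probabilities

The published input table omits the transition probabilities out of
*well* (well→complication for ICD; well→hospitalization and well→death
per arm). `calibrate()` recovers them by minimising the sum of squared
*relative* residuals between the deterministic model's discounted
lifetime (cost, QALY) pair and the published per-arm outputs — relative,
because costs and QALYs differ by three orders of magnitude. The arms
share no free parameters and are fitted independently (3 ICD, 2 drug
parameters). Each free probability is bounded in [0, 0.5]: annual event
risks above 50% from a "well" state are clinically implausible.

The optimiser is a deterministic multistart of bounded quasi-Newton
(L-BFGS-B) local searches from a 3^k grid (each bound and the midpoint
per dimension). A derivative-free search was considered; the objective
is smooth in the free probabilities, so quasi-Newton converges faster
and the multistart handles multimodality. With 3 ICD parameters and
only 2 targets the optimum can be non-unique; the reported solution is
the first best in the deterministic start order, and tests assert
recovered *outputs*, not parameter values, for that arm.

**What calibration can and cannot reproduce.** The drug arm converges
to residuals below 0.1%. The ICD arm does not: the published pair
($41,135, 12.63 QALYs) lies outside the model's attainable set under
the published inputs. The reason is structural. Every live ICD state
costs $4,022–$4,296 per utility unit per year, and because costs are
discounted harder (6%) than outcomes (3%), any long-lived cohort
realises *less* than that ratio — a constant-mortality cohort pinned to
12.63 QALYs yields at most ≈ $36–38k, about 7% short. A dense grid scan
over the three free probabilities confirms the shortfall is a frontier,
not an optimiser failure:

```{r frontier, eval = FALSE}
p <- load_parameter_table()
v <- base_values(p)
best <- -Inf
for (a in seq(0, .5, .02)) for (b in seq(0, .5, .02)) for (d in seq(0, .5, .02)) {
  if (a + b + d > 1) next
  v[c("tp_well_compl_icd", "tp_well_hosp_icd", "tp_well_death_icd")] <- c(a, b, d)
  r <- run_arm(p, "ICD", v)
  if (abs(r$discounted_qaly - 12.63) < 0.13)
    best <- max(best, r$discounted_cost)
}
best  # ~38,100 < 41,135
```

Notably, truncating the horizon at ~19 annual cycles (age 57 plus 19 is
close to Iranian life expectancy) with near-zero well mortality
reproduces the ICD pair almost exactly
(`run_arm(p, "ICD", v0, max_cycles = 19)` with all free exits at 0
gives ≈ $41,300 and 12.9 QALYs), suggesting the original TreeAge model
effectively stopped at life expectancy rather than running to cohort
extinction. The package keeps the lifetime (100-cycle/absorption)
horizon as specified and reports the ICD calibration honestly as
non-converged with its residual diagnostics; the corresponding
acceptance test is left failing by design. The bundled default
parameter file carries the constrained optimum
(well→complication ≈ 0.205, others 0 for ICD;
well→hospitalization ≈ 0.207, well→death ≈ 0.0026 for the drug arm),
which preserves the published verdict: base-case ICER ≈ $17,200/QALY,
above the $13,002 threshold.

## What the synthetic generator emulates — and what a green test shows

`random_valid_parameter_set()` draws structurally valid input tables:
row-stochastic exit probabilities, beta-feasible SDs (capped at
0.8·√(m(1−m))), positive costs, utilities in (0,1). It emulates the
*shape* of the published table, not its clinical content — generated
death risks and costs are uniform draws over plausible ranges, with no
correlation between costs and severity and no age structure. Green
property tests over these sets establish that the engine conserves the
cohort, that death occupancy is monotone, and that discounting behaves
— they do not validate the clinical realism of any particular input.
Likewise the toy two-state chains validate the accrual arithmetic
against geometric-series closed forms, nothing more.

## Numerical choices

- Row-stochasticity and cohort conservation are enforced to 1e-9;
  method-of-moments round trips to 1e-9; engine-vs-closed-form oracle
  agreement to 1e-6 at an absorption tolerance of 1e-10.
- Probability and utility clamping is hard at [0,1]; clamp events are
  counted, never silent.
- Ratios are reported at full precision and rounded to whole dollars
  only for display, matching the published table's integer presentation.
- Tornado ties break lexicographically so output order is total.

## Known limitations

- The published net-monetary-benefit column back-solves to a
  willingness-to-pay of ≈ $16,650/QALY, not the stated $13,002; the
  package reports NMB at the configured threshold and makes no attempt
  to match that column. The published incremental QALY (1.35) likewise
  disagrees with its own per-arm values (12.63 − 11.29 = 1.34); the
  arithmetic value is used.
- The published 40% probability of cost-effectiveness at the threshold
  is not exactly recoverable (the original free parameters and the
  sampled-parameter list are unpublished); the package reports its own
  CEAC value instead.
- No background mortality, no age/sex stratification, no patient-level
  microsimulation, no multi-strategy frontier, no EVPI.
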