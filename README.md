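# icdcea

Markov cohort cost-effectiveness analysis of implantable cardiac
defibrillator (ICD) therapy versus pharmaceutical therapy for cardiac
arrhythmia, from the perspective of the Iranian health system.

## The problem

Patients treated for cardiac arrhythmia either receive an ICD or are
managed with anti-arrhythmic drugs. ICD therapy is far more expensive but
extends life and quality of life. Whether the extra cost is worth the
extra benefit is a resource-allocation question answered with a
cost-effectiveness analysis: simulate the lifetime costs and
quality-adjusted life-years (QALYs) of each strategy and compare the
incremental cost-effectiveness ratio (ICER) with a willingness-to-pay
(WTP) threshold — here three times 2021 GDP per capita, **$13,002 per
QALY** (all amounts in USD at the 2021 official rate of 42,000 Rials/USD).

## The model

A cohort state-transition (Markov) model with annual cycles run to a
lifetime horizon. The ICD arm has five states — *well*,
*hospitalization*, *complication*, *device rejection*, *death* — and the
drug arm three (*well*, *hospitalization*, *death*). Death is absorbing.
Each cycle the cohort fractions move by the arm's transition matrix
`P`, so `x_{t+1} = x_t P`, and discounted rewards accrue:

    Cost  = Σ_t Σ_s x_t(s) · c(s) / (1 + r_c)^t        r_c = 6%
    QALY  = Σ_t Σ_s x_t(s) · u(s) / (1 + r_o)^t        r_o = 3%

plus a one-time death cost applied to the fraction newly entering death.
The headline statistic is

    ICER = (Cost_ICD − Cost_drug) / (QALY_ICD − QALY_drug)

together with each arm's average ratio (ACER = Cost/QALY) and net
monetary benefit (NMB = λ·QALY − Cost at WTP λ).

Transition probabilities, state costs and utilities come from the
published input table; uncertain parameters carry beta (probabilities,
utilities) or gamma (costs) distributions fitted from their (mean, SD)
by the method of moments. The exit probabilities of the *well* state
were not published; `calibrate()` recovers them by least squares against
the published lifetime outputs (see the methods vignette — the drug arm
is reproduced to <0.1%, the ICD arm's published pair is shown to be
unreachable under the published inputs).

Sensitivity analysis: one-way (tornado) and two-way deterministic
analyses over 95%-CI parameter ranges, and a seeded 1000-iteration
probabilistic analysis (PSA) feeding the cost-effectiveness plane and
acceptability curve (CEAC).

## Worked example

```r
library(icdcea)
cmd_run()
```

```
icdcea 0.1.0 | dr_cost=0.060 dr_outcome=0.030 wtp=13,002 max_cycles=100 half_cycle=FALSE init=WELL seed=1

               Strategy  QALY Cost($) ACER($/QALY)  NMB($)
                    ICD 13.04  38,778        2,973 130,829
 Pharmaceutical therapy 11.29   8,591          761 138,195

Incremental: cost $30,187, effect 1.76 QALYs
ICER: $17,199/QALY (NE)
Verdict: ICD is not cost-effective at WTP $13,002/QALY
```

Reading: over a lifetime, ICD therapy costs ~$30,200 more and yields
~1.76 more QALYs than drug therapy, i.e. ~$17,200 per extra QALY —
above the $13,002 threshold, so ICD therapy is not cost-effective at
that WTP (NE = north-east quadrant of the CE plane: costlier, more
effective). The published analysis reports the same verdict with ICER
$24,286/QALY from per-arm outputs the calibration chapter of the
vignette discusses in detail.

More:

```r
psa <- cmd_psa(n_iter = 1000, seed = 1, out_dir = "out")   # PSA + CEAC + plots
tor <- cmd_tornado(out_dir = "out")                        # tornado CSV + plot
cal <- cmd_calibrate(out_dir = "out")                      # calibration report
```

or from the shell via the bundled launcher:

```sh
Rscript inst/cli/icdcea run --wtp 13002
Rscript inst/cli/icdcea psa --n-iter 1000 --seed 1 --out-dir out
```

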