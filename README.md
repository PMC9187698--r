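# icpcast

Probabilistic forecasting of dangerously elevated intracranial pressure
(ICP) for patients monitored in neuro-intensive care.

Severe traumatic brain injury is routinely managed by continuous ICP
monitoring, with treatment aimed at keeping pressure below 20 mmHg.
Episodes above that limit cause secondary injury, so clinicians want a
warning *before* the pressure rises, not an alarm when it already has.
`icpcast` implements a simple, explainable forecaster for that task: given
the preceding hour of a patient's minute-resolution ICP, it predicts, for
each 10-minute interval of the *next* hour, whether that interval's mean
ICP will be below ("1", normal) or at/above ("2", severe) 20 mmHg.

It is aimed at biostatisticians and clinical-data scientists who want a
transparent baseline forecaster for pressure time series, and includes a
synthetic cohort generator so the whole pipeline can be exercised, tested
and benchmarked without access to patient recordings.

## The model

Each 10-minute interval is summarised by two statistics: its **mean** ICP
(the response, dichotomised at 20 mmHg into classes 1/2) and its **third
quartile** ICP<sub>3Q</sub> (the predictor, discretized into three levels:
1: ICP<sub>3Q</sub> < 15, 2: 15 ≤ ICP<sub>3Q</sub> < 20,
3: ICP<sub>3Q</sub> ≥ 20 mmHg).  With *x*<sub>t</sub> the level of
interval *t*, the class of interval *t + k* (horizons *k* = 1…6) is
predicted from the six-interval history
**x** = (x<sub>t−5</sub>, …, x<sub>t</sub>) by Bayes' rule,

    P(y_{t+k} = c | x)  ∝  P(y_{t+k} = c) · P(x | y_{t+k} = c),   c ∈ {1, 2},

a dynamic naive Bayes classifier whose priors and class-conditional
history tables are estimated by (optionally Laplace-smoothed) maximum
likelihood — closed-form counts, no iterative fitting.  The
class-conditional P(**x** | c) is factorized per lag position by default
(`per_lag`); the unfactorized 3⁶-cell `joint` table is also available.

Because severe intervals are rare (~18% of monitoring time), the plain
maximum-a-posteriori rule under-calls them.  The **enhanced** rule
handicaps the majority class with a balancing factor α ∈ (0, 1]:

    predict 1  iff  α · P(1 | x) > P(2 | x)      (ties → 2).

With α = 0.65 and posterior (0.6, 0.4), the weighted class-1 score is
0.65 · 0.6 = 0.39 < 0.40, so class 2 is predicted.  α is chosen on a grid
(0.50–0.85, step 0.05) by maximizing the total accuracy gain

    T = A·f₁(α) + w·(1 − A)·f₂(α),    T > 0,

where *A* is the class-1 fraction, *f*<sub>i</sub>(α) the change in
class-*i* accuracy relative to α = 1, and *w* (default 2) the clinical
weight of a missed severe episode.  Defaults: α = 0.60, w = 2.

## Worked example

```r
library(icpcast)

# a synthetic 5-patient cohort with persistent (2 h mean dwell) elevated
# episodes at the typical ~18% elevated fraction
cfg    <- cohort_config(n_patients = 5, hours_per_patient = 100,
                        dwell_elev = 120, elev_frac = 0.18, seed = 42)
cohort <- generate_cohort(cfg)

tables    <- lapply(cohort, function(s) make_intervals(clean_series(s)))
intervals <- do.call(rbind, tables)
windows   <- make_windows(intervals)   # 13,882 (history, response) pairs

model <- fit_cpt(split_random(windows, 0.8, seed = 42)$train)
model
#> <cpt_model> dynamic naive Bayes ICP forecaster
#>   history d1 = 6 intervals, horizons m = 6, mode = per_lag, lambda = 1
#>   enhancement: alpha = 0.6, w = 2
#>   P(severe) by horizon: 0.135 0.136 0.135 0.133 0.132 0.130

# an hour that ends in three severe-level intervals
posterior(model, c(1, 1, 2, 3, 3, 3), k = 1)
#>           1           2
#> 0.006104499 0.993895501
```

The prior probability of a severe interval is ~0.13, but after an hour
ending in three level-3 intervals the posterior for the next 10 minutes is
0.994 — the model has learned that elevated episodes persist.

```r
report <- evaluate_split(windows, seed = 42, alpha = 0.60, B = 1000)
subset(report$results, horizon %in% c(1, 6))
#>    horizon class   method  accuracy  ci_lower  ci_upper   n
#> 1        1     1  general 0.9605911 0.9408867 0.9778325 406
#> 2        1     2  general 0.7936508 0.6984127 0.8888889  63
#> 3        1     1 enhanced 0.9556650 0.9359606 0.9753695 406
#> 4        1     2 enhanced 0.8571429 0.7777778 0.9365079  63
#> 21       6     1  general 0.9052369 0.8778055 0.9302369 401
#> 22       6     2  general 0.5737705 0.4586066 0.7049180  61
#> 23       6     1 enhanced 0.9027431 0.8728180 0.9302369 401
#> 24       6     2 enhanced 0.6557377 0.5409836 0.7704918  61
```

Class-1 accuracy (specificity) stays around 0.90–0.96 at every horizon;
class-2 accuracy (sensitivity) is highest for the nearest horizon and
degrades further out, and the α = 0.60 enhancement buys sensitivity
(0.794 → 0.857 at the first interval) at a small specificity cost —
exactly the trade the balancing factor is designed to make.  Patient-level
generalisation is assessed with `loocv(tables)` (leave-one-patient-out,
proportion-weighted summaries).

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/icpcast`:

```sh
Rscript inst/cli/icpcast simulate --patients 10 --hours 200 --seed 1 --out sim/
Rscript inst/cli/icpcast preprocess --in sim/cohort.csv --out pre/
Rscript inst/cli/icpcast train --windows pre/windows.csv --out model.json
Rscript inst/cli/icpcast predict --model model.json --windows pre/windows.csv --out pred.csv
Rscript inst/cli/icpcast evaluate --mode loocv --in sim/cohort.csv --out report/
```

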