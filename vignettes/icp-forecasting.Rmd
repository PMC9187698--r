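---
title: "Forecasting elevated intracranial pressure: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting elevated intracranial pressure: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpcast)
```

## The clinical problem

Intracranial pressure (ICP) above 20 mmHg sustained over minutes-to-hours
causes secondary brain injury in intensive-care patients, and treatment
guidelines aim to keep pressure below that limit.  A forecaster that flags
a *coming* elevation gives the treating team time to act.  `icpcast`
predicts, for each 10-minute interval of the next hour (horizons
$k = 1, \dots, 6$), whether that interval's mean ICP will reach 20 mmHg,
using only the preceding hour of the same patient's minute-resolution ICP.

## From minutes to features

Raw recordings arrive as one pressure value per minute, with gaps where
artifacts (probe handling, transport) were removed.  The pipeline is:

1. **Gap handling** (`clean_series`): missing runs of at most
   `max_gap_minutes` (default 2) flanked by observations are linearly
   interpolated; longer runs stay missing.  The default tolerates brief
   probe artifacts while refusing to invent data across real dropouts —
   long gaps later invalidate the intervals they touch, so no prediction
   window bridges them.
2. **Interval statistics** (`make_intervals`): consecutive 10-minute bins
   from each patient's first recorded minute (no calendar alignment — the
   recording itself defines the grid).  Per bin, the *mean* ICP is the
   response statistic, dichotomised at 20 mmHg into class 1 (normal) /
   class 2 (severe); the *third quartile* is the predictor statistic,
   discretized as level 1 ($Q_3 < 15$ mmHg), 2 ($15 \le Q_3 < 20$) or 3
   ($Q_3 \ge 20$).  Both boundaries map upward (a bin at exactly 20 mmHg
   is severe, level 3).  The third quartile reacts earlier than the mean
   when only part of a bin is elevated, which is why it is the predictor.
3. **Windows** (`make_windows`): every anchor interval $t$ preceded by
   $d_1 = 6$ consecutive valid intervals contributes one row per horizon
   $k$ whose response interval $t+k$ is valid.  Anchors near the end of a
   recording contribute only the horizons that fit.

Two conventions deserve a note.  The third quartile of ten samples
depends on the quantile convention; we fix linear interpolation between
order statistics (R's type 7), with the type exposed as an argument
because conventions genuinely differ at $n = 10$.  A bin is *valid* when
at least 8 of its 10 minutes are observed: enough to estimate a stable
mean, while tolerating the short dropouts the interpolation step refuses
to fill.

## The forecaster

For a history $\mathbf{x} = (x_{t-5}, \dots, x_t)$ of discretized levels,
the posterior for the class of interval $t + k$ is Bayes' rule

$$
P(y_{t+k} = c \mid \mathbf{x}) =
\frac{P(y_{t+k} = c)\, P(\mathbf{x} \mid y_{t+k} = c)}
     {\sum_{c'} P(y_{t+k} = c')\, P(\mathbf{x} \mid y_{t+k} = c')},
\qquad c \in \{1, 2\},
$$

with one prior and one conditional table per horizon, estimated by
maximum likelihood with pseudo-count smoothing $\lambda$:
$\hat P(y = c) = (n_c + \lambda)/(n + 2\lambda)$ and analogously per
conditional cell.

**Factorization.**  $P(\mathbf{x} \mid c)$ over six ternary lags has
$3^6 = 729$ cells per class.  The default `per_lag` mode assumes the lag
positions conditionally independent given the class — the naive-Bayes
reading — leaving $6 \times 3$ cells per class, robust at clinical data
sizes (a few thousand windows per horizon).  The unfactorized `joint`
mode is retained both for completeness and because with $\lambda = 0$ it
reduces exactly to contingency-table Bayes, which the test suite exploits
as an independent oracle.  At the cohort sizes the synthetic generator
produces, the two modes rank histories similarly; `per_lag` is the
default because the joint table is badly undersampled at
729 cells per class.

**Smoothing.**  Default $\lambda = 1$ (add-one), so no history has
probability zero at prediction time; $\lambda = 0$ reproduces pure
maximum likelihood for the oracle tests.  If, under $\lambda = 0$, a
queried history has zero likelihood under both classes, the posterior is
undefined; the implementation returns the prior with a warning rather
than failing.

**Missing lags.**  Because the model is generative, a partially observed
history is handled by marginalizing the missing positions: in `per_lag`
mode their factors drop out; in `joint` mode the conditional is summed
over all completions.  A fully missing history returns the prior,
flagged.  This is a genuine advantage over regression-type forecasters,
which need complete predictor vectors.

**Decision rules and ties.**  The *general* prediction is the MAP class.
The *enhanced* prediction handicaps the majority class: predict 1 only if
$\alpha P(1 \mid \mathbf{x}) > P(2 \mid \mathbf{x})$, $\alpha \in (0,1]$.
All ties — including the MAP tie at posterior (0.5, 0.5) — resolve to
class 2, the clinically conservative alert.

## Choosing the balancing factor

Severe intervals are the minority (~18%), so accuracy-driven fitting
under-calls them.  $\alpha$ is selected on the grid $0.50, 0.55, \dots,
0.85$ by maximizing the total gain

$$ T(\alpha) = A f_1(\alpha) + w (1 - A) f_2(\alpha), $$

where $A$ is the fraction of class-1 responses, $f_i(\alpha)$ the change
in class-$i$ accuracy relative to $\alpha = 1$ (so $f_1 \le 0 \le f_2$),
and $w \ge 1$ the clinical weight of the severe class ($w = 2$: a missed
elevation is twice as costly as a false alarm).  The chosen $\alpha$
maximizes $T$ subject to $T > 0$; among ties the *largest* $\alpha$ wins
(least intervention), and if no grid point beats the baseline the rule
falls back to $\alpha = 1$.  Design choices that were genuinely open:

* $f_i$ is evaluated per horizon and the shared $\alpha$ maximizes the
  mean $T$ across horizons (per-horizon maximizers are also reported);
  one shared factor keeps the bedside rule simple.
* Selection runs on the *training* split only, never on held-out data —
  the threshold is a fitted parameter and tuning it on the test set would
  leak.
* $A$ is computed within each horizon's validation rows; with complete
  windows the horizons share essentially the same class marginal.

Decreasing $\alpha$ can only move predictions from class 1 to class 2,
so sensitivity is non-decreasing and specificity non-increasing along the
grid — a mechanical monotonicity the test suite asserts, and the reason
the enhanced rule at $\alpha < 1$ can never have lower sensitivity than
the MAP rule on the same predictions.

## Evaluation designs

Two designs mirror how such a forecaster is validated:

* **Random 80/20 split** (`evaluate_split`): within each patient, 80% of
  anchors train the model and 20% are held out.  Whole anchors travel
  with all six horizon rows, so the same future interval never informs
  both sets.  The train count is `floor(n * 0.8 + 0.5)` (round half up).
  Per horizon, class and rule, accuracy is reported with a percentile
  bootstrap CI (default $B = 1000$, level 0.95) obtained by resampling
  the row-level correctness indicators within the cell — the resampling
  unit matches the cell the CI describes.
* **Leave-one-patient-out** (`loocv`): the model is fitted on all other
  patients and evaluated on the held-out patient's continuous series —
  the clinically realistic test, since a new patient contributes no
  training data.  Cohort summaries weight each patient's class-$c$
  accuracy by that patient's share of class-$c$ responses (normalized
  over patients), so a patient with three severe intervals does not get
  the same vote on sensitivity as one with three hundred; min–max ranges
  across patients are reported alongside.

Accuracies are defined classically: specificity is the fraction of true
class-1 rows predicted 1, sensitivity the fraction of true class-2 rows
predicted 2.  Cells with an empty denominator are flagged undefined
rather than silently dropped.

## The synthetic cohort generator

No public ICP recordings exist at minute resolution, so the package ships
a generator (`generate_cohort`) that emulates the statistical structure
the model assumes: a two-state first-order Markov regime chain per minute
(normal / elevated), Gaussian emission noise within regime, clipping at 0
mmHg, and a missingness process with Bernoulli gap starts and geometric
gap lengths.  Defaults: normal regime 13 ± 2 mmHg, elevated 24 ± 3 mmHg,
mean dwell 90 min normal / 20 min elevated — giving the ~82/18 class
imbalance typical of treated severe-TBI cohorts and a unimodal pressure
density with a right shoulder — and 2.5% missingness in gaps of mean 3
minutes, matching the artifact fraction typically removed from such
recordings.  The stationary elevated fraction is closed-form,
$p_{\uparrow}/(p_{\uparrow} + p_{\downarrow})$, which the tests compare
against the realized minute fractions.

What the generator does *not* emulate: pulse and B-wave morphology,
plateau waves, drift in regime means, treatment feedback (real ICU data
are *intervened on* whenever pressure rises), or inter-patient
heterogeneity in baseline pressure.  Passing tests on synthetic cohorts
therefore demonstrate that the pipeline is correct and that the decision
theory behaves as designed — not that the reported accuracies transfer to
real patients.

`generate_interval_windows` samples directly from a specified `per_lag`
model (class from the prior, each lag from its class-conditional), which
is the exact generative process the fitter assumes; it backs the
parameter-recovery tests (20,000 windows, all probabilities recovered
within ±0.02 of truth, comfortably above the binomial standard error at
~10,000 draws per class).

## Problem sizes and runtime

The validation suite runs cohorts of 4–6 patients × 30–48 h for the
behavioural properties (ten independent seeds where a property is
stochastic, e.g. horizon degradation on cohorts with 2 h mean elevated
dwell), and one full-scale closure run of 10 patients × 200 h — about 1.2
million simulated minutes, 56,000 windows — through simulate →
preprocess → fit → α selection → leave-one-out, which completes in a few
seconds on one CPU because fitting is counting and prediction is table
indexing.

## Known limitations

* Accuracy on real cohorts cannot be established here; only structural
  and behavioural correctness is tested (see the generator caveats).
* The per-lag factorization ignores within-history autocorrelation given
  the class; it is a deliberate bias/variance trade at clinical data
  sizes.
* Horizons are predicted independently; the six per-horizon predictions
  for one anchor are not constrained to be temporally coherent.
* The 10-minute grid starts at the first recorded minute; a different
  anchoring shifts bin boundaries and can flip borderline intervals.
* Waveform-level (125 Hz) artifact detection is out of scope: the package
  assumes artifacts were removed upstream and sees only minute values.
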