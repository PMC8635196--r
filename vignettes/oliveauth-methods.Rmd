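---
title: "Methods: censored elemental fingerprints, PLS-DA and repeated double cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored elemental fingerprints, PLS-DA and repeated double cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

oliveauth implements a complete chemometric authentication workflow for
extra-virgin olive oil (EVOO) from multielement (ICP-MS) concentration
profiles: censoring-aware preprocessing, nonparametric univariate
comparison, an antioxidant index, and a two-class PLS-DA classifier
validated by repeated double cross-validation (rDCV). This vignette is the
package's own account of the statistical choices behind each stage — what
is assumed, what is tunable, and what the defaults mean.

```{r setup}
library(oliveauth)
```

## The data model

The measured object is a samples-by-elements concentration table in ug/kg.
Two features dominate its statistics:

* **Left-censoring.** Each element has a method detection limit (MDL);
  a measurement below it is only known to be "below MDL". Detection rates
  in real EVOO panels span 0% (Tl at MDL 0.06 ug/kg) to 100% (Ca, Cr, Mg,
  Mn, Ni, P, Ti, Zn).
* **Right skew.** Concentrations span orders of magnitude between samples;
  medians sit far from maxima for nearly every element. This is the reason
  the univariate stage is nonparametric.

Tables travel in long form (`sample_id`, `replicate`, `element`, `value`,
`censored`, `mdl`), so every cell carries its censoring state and detection
limit; `pivot_concentrations()` produces the wide matrix the classifiers
consume.

## Synthetic data generator

Per-sample raw data of the reference survey are not published, so the
package ships a generator (`generate_dataset()`) that emulates the survey's
*statistical* structure and makes every downstream stage testable:

* per element, true concentrations are log-normal; `default_panel()`
  derives `log_mean`/`log_sd` for 45 elements from the published MDLs,
  medians, detection percentages and maxima (n = 237), so simulated
  detection rates and ranges reproduce the survey's;
* class membership shifts the log-mean additively (`ClassEffect`s); the
  default effects encode the reported regional pattern (northern oils
  higher in Fe, Pr, Na, P, Cs, U; Lazio enriched in Cd, La, Rb);
* every sample receives two analytical replicates with multiplicative
  log-normal noise (relative SD `replicate_cv`, default 5%, a typical
  ICP-MS repeatability); censoring is applied to each replicate
  independently, before averaging, because detection is a property of the
  individual measurement;
* DPPH% is a logistic squashing of a weighted sum of element z-scores
  (log scale) plus noise, bounded in (0, 100) by construction — the default
  links mirror the elements reported to correlate with radical-scavenging
  activity (Al, Ca, Fe, V, Zr, weakly Ba and Ni);
* the default class sizes are the 15 regional counts of the survey
  (24 Lazio vs 14 Abruzzo vs 79 Tuscany ...), so realistic unbalance is
  represented;
* one global seed is expanded into independent per-element and per-stage
  substreams, so adding an element never perturbs unrelated draws.

The generator does **not** emulate instrument drift, spike recoveries,
inter-element covariance (elements are independent by default — real
geochemical data are correlated), or region-specific censoring patterns.
Passing tests on generated data therefore demonstrate the correctness and
calibration of the *procedures*, not field performance on real oils.

## Preprocessing

The order of operations is: impute (per replicate) -> average replicates ->
filter by detection -> autoscale. Imputing before averaging makes the mean
well defined when one replicate is censored and the other detected.

* **MDL/2 substitution** (`substitute_censored()`): every censored cell
  becomes exactly `mdl/2`, the standard convention for trace-element
  statistics. The censoring mask is preserved, so the operation is
  idempotent and provenance survives. More sophisticated censoring
  estimators (Kaplan-Meier, ROS, ML) are deliberately out of scope.
* **Detection filter** (`filter_by_detection()`): an element enters a
  model only if at least 70% of the samples in scope are detected
  (boundary inclusive). The filter is recomputed per two-class comparison
  on the samples of those two classes; a global filter would import other
  classes' detection patterns into the model.
* **Autoscaling** (`fit_autoscale()`/`apply_autoscale()`): per-element
  mean/SD with the sample (n−1) convention. Parameters are always fitted
  on training rows and applied to held-out rows; constant columns raise an
  error naming the element.

## Univariate stage

Group comparison uses the tie-corrected Kruskal–Wallis test (heavy ties are
guaranteed by MDL/2 imputation) with the chi-square approximation, at
alpha = 0.05. The pairwise post-hoc is Dunn's z-test on the joint ranks
with Bonferroni adjustment — the default pairwise follow-up for
Kruskal–Wallis in mainstream statistical software; the adjustment method is
configurable. A fully degenerate comparison (all values identical) returns
H = 0, p = 1 by convention.

DPPH% is `(A0 − AS)/A0 × 100` from blank and sample absorbances; negative
values (sample absorbance above the blank) are reported with a warning, not
clipped, because they flag assay failures. Element–DPPH association uses
Spearman rank correlation by default, consistent with the nonparametric
framing (Pearson by flag), computed on imputed values; |r| < 0.4 is labelled
"low" and 0.4–0.768 "moderate", following the conventional reading of such
associations in EVOO surveys. The MRL screen compares measured values
against regulatory ceilings (100 ug/kg for As, Cu, Pb; 3000 ug/kg for Fe)
with an inclusive boundary; censored cells trivially comply.

## PLS-DA

Two-class discrimination is PLS1 regression on a dummy response: 1 for
class 1, 0 for class 2. The algorithm is NIPALS with X- and y-deflation;
with a single response the inner iteration is exact, so no convergence
tolerance is needed. Weight vectors are unit-norm; with as many components
as the rank of X, the coefficients equal the least-squares solution (an
identity the test suite checks to 1e-8 against the normal equations).

Because the predicted response is real-valued, a decision threshold is
derived by one-dimensional LDA on the training predictions: with class
means m1 > m2, pooled within-class variance s², and priors taken from the
training frequencies,

    y_thres = (m1 + m2)/2 + s² · ln(pi2/pi1)/(m1 − m2),

the crossing point of the two prior-weighted Gaussian densities. Training
frequencies are the default priors because the surveyed class sizes are
strongly unbalanced; equal priors are a flag. A sample is predicted as
class 1 when its response strictly exceeds the threshold — an exact tie
goes to class 2. The single canonical variate is the predicted response
re-centred at the threshold, so the sign of a score is the predicted class.

Coefficients are reported in the autoscaled space, where their signs and
magnitudes are comparable across elements. VIP scores use the standard
formula `VIP_j = sqrt(p · sum_a ssy_a w_ja² / sum_a ssy_a)`; the mean of
squared VIPs is exactly 1.

## Repeated double cross-validation

`run_rdcv()` wraps the classifier in two nested, stratified
cross-validation loops, repeated over `n_runs` random splits (defaults: 50
runs, 10 outer folds, 5 inner folds — the published settings). Per outer
fold, autoscaling is refitted on the outer-training rows only; the inner
loop picks the number of latent variables by minimising the pooled inner-CV
misclassification count (the end task is classification, so the selection
criterion is the classification error rather than the RMSE of the dummy
response), ties broken toward fewer components; the searched range defaults
to `min(10, rank bound)`. Stratification keeps both classes in every
training fold, which unstratified 10-fold splitting cannot guarantee at
sizes like 24 vs 14. The detection filter runs once on the full two-class
subset before the loops: the element panel must be constant across folds
for parameter distributions to be comparable, and the filter sees only
detection masks, never labels — a deliberate, disclosed exception to strict
in-loop refitting.

Figures of merit — accuracy, per-class sensitivities, and their unweighted
average (mean correct classification rate, robust to unbalance) — are
computed per run from the union of the outer-fold predictions (each sample
is predicted exactly once per run) and aggregated as mean ± SD over runs.
Per-sample canonical scores get empirical 95% intervals (2.5/97.5
percentiles over runs), the data behind the classic score-interval plot
(`autoplot(result, type = "scores")`).

### Which variables matter, and how the intervals are calibrated

The models of all runs × outer folds provide an empirical distribution for
every element's coefficient. A natural impulse is to call an element
significant when the 2.5–97.5 percentile band of that distribution excludes
zero, but that band is **not** a confidence interval for the coefficient:
fold models share roughly 90% of their training rows, so the spread of the
model distribution understates sampling variability by about `sqrt(k − 1)`
(k outer folds). Used directly, the percentile rule flagged 40–60% of
pure-noise elements in effect-free simulations.

`significant_variables()` therefore treats each run's outer-fold models as
delete-d jackknife replicates: the grouped jackknife variance
`(k−1)/k · sum_j (b_j − mean(b))²`, averaged over runs, estimates the
sampling variance of the coefficient. The default interval additionally
(i) shares the error rate across the element panel (Bonferroni), since
"which elements matter" is a family of p simultaneous questions, and
(ii) requires a mean VIP score above 1, the standard relevance rule —
both importance readings (coefficient sign/size and VIP) must agree. In
simulation this combination yields a ~0% false-flag rate on effect-free
data while recovering a 5-element signature separated by ≥3 within-class
SDs exactly, with correct signs, in ≥90% of generator seeds. The raw
percentile band remains available (`method = "percentile"`) for
descriptive plots.

Null calibration itself is assessed on the permutation-null *mean*: the
cross-validated accuracy of a single label permutation scatters around
chance with an SD of several points (the fitted models partially recover
whichever chance association that permutation realises), so the package's
acceptance checks average over 10 permutations.

## Problem sizes used by the checks

The shipped checks run the procedures at sizes a laptop handles in minutes:
calibration uses one effect-free 100 × 20 dataset under 10 label
permutations with the full 50 × 10 × 5 rDCV; recovery uses twenty 60 × 20
datasets with 5 shifted elements (log-normal, `log_sd` 0.2, log-shift 1.0 ≈
3.1 raw-scale SDs); the end-to-end pipeline runs the full 237 × 45 survey
geometry with the published regional class sizes and one classification
pair (Lazio vs Abruzzo, 24 vs 14).

## Known limitations

* MDL/2 substitution biases low-detection elements toward their MDLs; the
  70% detection filter limits, but does not remove, imputation artifacts in
  the models (the reason the filter exists).
* Elements are simulated independently; recovery rates on correlated real
  panels will differ, typically for the worse.
* The jackknife interval treats the chosen number of latent variables as
  part of the resampled procedure; strong selection instability widens the
  intervals (honestly) rather than biasing them.
* Only two-class models are provided, as in the underlying workflow;
  multi-class PLS2-DA is out of scope.
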