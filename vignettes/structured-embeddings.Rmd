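---
title: "Structured deep embeddings for longitudinal laboratory data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured deep embeddings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Electronic-health-record laboratory data are high-dimensional, redundantly
coded, irregularly sampled and mostly missing. `strudem` implements a family
of hierarchy-constrained neural embedding models that compress such data into
a handful of *composite indices* — single learned scalars summarising
clinically related measurement groups, in the way BMI summarises height and
weight — while keeping the network's information flow readable.

The hierarchy has three levels. Level 1 is the individual lab variable: each
variable's binned time series is embedded by an *independent* two-layer
perceptron into one scalar. Level 2 bundles redundant variables ("combos" —
the same analyte reported under different conventions): each combo maps its
member variables' scalars, and only those, to one scalar. Level 3 groups
combos into composite indices under a *grouping strategy*: expert organ
systems (`g1`) or connected components of the thresholded combo-correlation
graph (`g2` at |r| > 0.3, `g3` at |r| > 0.4, with all isolated combos pooled
into one residual composite). A single linear layer followed by log-softmax
turns the final embedding vector into a binary risk prediction. The *base*,
*combo* and *composite* models stop at levels 1, 2 and 3 respectively, so
their final widths on the packaged 206-variable taxonomy are 206, 32, and
5/3/7 (strategies g1/g2/g3).

Because each sub-network is constructed only over its members, cross-group
connections are structurally absent rather than merely penalised: the
gradient of any group embedding with respect to a non-member input variable
is identically zero. The test suite checks this by exact finite differences.
We chose construction over weight masking precisely so the contract is exact.

The per-variable sub-network is `bins -> 16 -> 1` with a tanh hidden layer
and linear output; grouping sub-networks are a linear map to one scalar
followed by tanh. The published model family specifies only the
one-dimensional output contract, so these depths and activations are this
package's own declared defaults, configurable via `buildModel()`.

## Cohort preparation

*Pre-diagnosis filtering.* Measurements at or after the index (diagnosis)
date are removed — `t < 0` strictly, so records at exactly `t = 0` are
dropped. Early-detection censoring keeps records *more than* `k` months
before the index, again strict. Months are fixed at 30.4375 days everywhere,
removing calendar ambiguity. Both filters are idempotent and compose
(`censor(k2) after censor(k1)` equals `censor(max(k1, k2))`), which the
suite verifies.

*Control index dates.* Cases lose a measurable fraction of their records to
the pre-diagnosis filter; controls have no diagnosis, so each control
receives a random index date calibrated so truncation removes, in
expectation, the same mean per-variable fraction `f`. With visit times
uniform over a lookback of `L` days, the index shift is drawn uniformly on
`[max(0, 2f - 1) L, min(1, 2f) L]`, whose mean is `f L` and whose endpoints
make the boundaries exact (`f = 0` removes nothing; `f = 1` precedes every
measurement). A uniform draw is one of several calibrations consistent with
matching an average reduction; it was chosen for analytic transparency.

*Tensorization.* The network consumes fixed-length grids: bin `b` (most
recent first) covers `[-b w, -(b-1) w)` months relative to the index, the
bin value is the within-bin mean, and empty bins are exactly 0 — the
zero-imputation convention. Values are standardized per variable first, so
the imputed 0 coincides with the variable mean on the model's input scale;
evaluation grids reuse the training-time scaling. No sequence encoding is
prescribed by the model family itself; fixed monthly bins over a 60-month
lookback (24 months in the desk-scale study) are the simplest encoding
compatible with independent per-variable weights.

*Propensity matching.* Separability — held-out accuracy of a logistic
classifier distinguishing cases from controls on baseline covariates alone —
is estimated by averaging up to 100 seeded fits on balanced resamples.
Controls are then matched 1:1 to cases by nearest neighbour on the logit of
the propensity score, without replacement and with no caliper (the matching
discipline is unstated upstream; this is the plainest choice). The
post-match estimate stops early once its running mean is within tolerance of
0.5. Whether the published 55% post-match figure was in-sample or held-out
is unstated, so `propensityMatch()` reports both.

## Training and evaluation

The protocol is 10 repeated experiments; each draws a fresh stratified 80/20
train/test split (a pure function of seed and repeat number), initialises
fresh weights, trains on the negative log-likelihood, and early-stops within
50 epochs by monitoring loss on the test set. Monitoring the same set that
is later reported is statistically improper but is the stated protocol of
this model family; a conventional three-way split is available via
`validationFraction` and is off by default. Optimisation uses Adam at
learning rate 1e-3 with batch size 32, patience 5 armed only after a
10-epoch floor, and an L2 weight penalty of 3e-3 — all unstated upstream,
fixed here and logged. The floor exists because on the initial loss plateau
minibatch noise can tick the monitored loss upward for several consecutive
epochs, and without the floor early stopping occasionally returns a
first-epoch snapshot of the deeper models before training has escaped
initialisation. The weight penalty
matters at desk scale: a few hundred patients cannot support thousands of
unpenalised per-variable weights, and without it the deeper models memorise
noise variables (perfect training AUROC, degraded held-out AUROC) while the
shallow base model, with its simpler function class, escapes largely
unharmed — breaking the hierarchy-parity property for reasons of estimation,
not architecture. AUROC is computed by the rank
(Mann-Whitney) method and AUPRC as average precision; a brute-force pairwise
oracle pins the former to 1e-9 in the tests. Early-detection performance
re-tensorizes censored records at `k` months and evaluates the frozen model
on each repeat's own held-out split (whether the upstream evaluation reused
its split or the full cohort is unstated; the held-out split is the
conservative reading).

## Cluster purity and its entropy

Embeddings are clustered by a full-covariance Gaussian mixture initialised
from seeded K-means and refined by EM, with hard assignment by maximum
responsibility. Cluster purity against the case/control labels is scored by
the total entropy
$$ -\sum_i \sum_j \frac{n_{ij}}{n_i} \log\frac{n_{ij}}{n_i} \; w_{ij}, $$
with natural logarithm and `0 log 0 = 0`. The per-term weight `w_ij` is
ambiguous as printed in this literature; we adopt the standard size-weighted
convention `w_ij = n_i / N` (configurable to uniform weights), under which
the score is 0 exactly when every cluster is pure and at most `log(#classes)`.
The printed summation is nonpositive as written, so the package reports its
negation: lower = purer on a nonnegative scale. The component count defaults
to 2 (the case/control subgrouping) and is configurable. t-SNE is provided
as a seeded plotting aid only; the entropy never uses it.

## Interpretability

`compositeImportance()` ranks composite indices by four classifiers —
logistic regression (absolute standardized coefficients), decision tree,
random forest and gradient boosting (split-criterion reduction scores) —
refit on seeded subsamples for dispersion, with scores normalised to sum to
one per method.

`layerShap()` explains the case log-probability at every hierarchy level:
the explained function is always the model's own downstream layers applied
to that level's embeddings, with a seeded background sample (default 50
patients) from the cohort itself. Attribution is interventional Shapley
value: exact subset enumeration up to 12 features, permutation sampling
above that. Both estimators satisfy additivity exactly by construction
(each permutation's marginal contributions telescope), so the suite can
assert per-patient additivity at machine precision. Mean `|SHAP|` per unit
is reported with its SD over patients, plus each unit's parent for
cross-layer linkage. `accumulatedShap()` sums base-model variable
attributions into composites for comparison with the composite model's own
level-3 report; the two generally differ because attribution depends on the
architecture. The explained output is the log-probability of the case class
— a single scalar, monotone in risk.

## Temporal trends

`windowedMeans()` averages each patient's measurements within ±2 months of
the anchor months 0, 3, 6 and 12 before the index (windows may overlap;
anchor 0's window is truncated by the pre-diagnosis filter). Missing windows
stay missing — these means feed regression, not the network. The trend
statistic regresses anchor means on time, oriented so that values rising
toward diagnosis give a positive slope, and divides the coefficient by the
normal-range diagonal `(high - low) / (anchor span)`: a series climbing from
the bottom to the top of its normal range across the span scores exactly 1,
and the statistic is invariant under joint affine rescaling of variable and
range. Group-level trends regress the per-anchor group means by default;
per-patient regression is an option (the pooled-versus-grouped choice is
unstated upstream).

## The synthetic study

No real cohort can ship with the package, so every stage is exercised on a
seeded synthetic study designed to emulate the relevant structure of
longitudinal EHR labs: Poisson-process visits (12/year), 70% per-visit
missingness, control trajectories stationary at the midpoint of each
variable's normal range with SD one quarter of the range width, and case
trajectories in designated signal composites drifting by 0.15 SD/month over
the final 24 months before the index — an analytically convenient stand-in
for the gradual pre-diagnosis biomarker changes this model family targets.
Two covariates confound labels through a stated discriminant link (age
shifted 0.9 SD, a binary comorbidity at 62% vs 38% prevalence), targeting
roughly 70% baseline separability so matching has measurable work to do.
The reference study simulates 200 cases and 300 controls over a 60-month
lookback, matches controls 1:1 down to a 400-patient analysis set, bins the
most recent 24 months monthly, and trains all three hierarchy levels under
the 10-repeat protocol; it completes in about two minutes on one CPU.

The generator's baselines-at-midpoint choice makes trend ground truth
analytic: drift `d` SD/month implies an adjusted slope of `d x span / 4`,
attenuated by a computable window-placement factor (~0.93 for the default
anchors). What the generator does *not* emulate — calendar-time coding
drift, demographic realism, non-Gaussian assay noise, informative visit
timing — bounds what green tests show about real data: they validate the
machinery and its contracts, not clinical performance.

## Numerical choices and limitations

Degenerate inputs are handled explicitly: constant combo columns are treated
as uncorrelated (with a warning) in correlation grouping; constant
embeddings get zero importance; empty mixture components trigger a re-seeded
retry; records beyond the lookback are dropped with a logged count; a
patient emptied by censoring keeps an all-zero grid. Ties in AUROC use
midranks. All randomness flows from explicit integer seeds, and pipeline
stage seeds are derived by hashing the global seed with the stage name, so
stages re-run identically in isolation.

Known limitations: embeddings are strictly one-dimensional by design; no
recurrent or attention-based sequence encoders; no multiple imputation
beyond zero-filling; correlation grouping bundles by connected components
(the weakest defensible closure of "correlated with each other") on absolute
Pearson correlation, both recorded as interpretations; and the t-SNE aid is
exact (O(n^2)) and meant for small cohorts.
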