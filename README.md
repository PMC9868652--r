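# strudem — structured deep embedding models for longitudinal lab data

Clinical laboratory data in electronic health records are high-dimensional,
redundantly coded, irregularly sampled and mostly missing — hard for a
clinician to scan and easy for an unconstrained neural network to overfit.
`strudem` is for biostatisticians and clinical-ML researchers who want risk
models whose internals stay readable: it compresses each patient's
longitudinal labs into a handful of **composite indices** — learned scalars
summarising clinically related measurement groups, the way BMI summarises
height and weight — and predicts a binary outcome from those indices alone.

## The model

A three-level taxonomy organises the inputs: individual variables (level 1)
are bundled into redundancy groups, *combos* (level 2), which a *grouping
strategy* partitions into composite indices (level 3) — either expert organ
systems (`g1`) or connected components of the thresholded combo-correlation
graph (`g2`: |r| > 0.3, `g3`: |r| > 0.4, isolated combos pooled into a
residual group).

The network mirrors the taxonomy. Each variable's binned series is embedded
by an independent perceptron into one scalar `e_v`; each combo maps its
members' scalars to one scalar; each composite likewise; a final linear
layer with log-softmax yields the prediction:

    e_v   = f_v(x_v)                      (bins -> 16 -> 1, per variable)
    e_c   = tanh(w_c' e_{v in c} + b_c)    (per combo)
    e_k   = tanh(w_k' e_{c in k} + b_k)    (per composite)
    log p = log_softmax(W e + b)

Sub-networks exist only over their members, so cross-group connections are
*structurally absent*: the gradient of any embedding with respect to a
non-member variable is identically zero. The *base*, *combo* and *composite*
models stop at levels 1, 2 and 3; on the packaged 206-variable taxonomy
their final widths are 206, 32, and 5 / 3 / 7 (strategies g1 / g2 / g3).

Around the models, the package implements the full study machinery:
a seeded synthetic-cohort generator (Poisson visits, heavy missingness,
group-structured case drift, confounded covariates); pre-diagnosis
filtering, early-detection censoring, zero-imputed monthly tensorization and
propensity-score matching; the 10-repeat / 80-20 / 50-epoch early-stopping
training protocol with AUROC/AUPRC; K-means-initialised Gaussian-mixture
clustering scored by size-weighted total entropy; four-classifier composite
importance and exact/permutation Shapley attribution per hierarchy layer;
and normal-range-adjusted temporal slopes.

## A worked example

```r
library(strudem)

tax <- syntheticTaxonomy()              # 20 vars -> 10 combos -> 5 organ groups
cfg <- generatorConfig(nCases = 60, nControls = 60, taxonomy = tax,
                       lookbackMonths = 24,
                       signalGroups = "liver function group",
                       driftPerMonth = 0.15, seed = 11)
sim <- simulateCohort(cfg)
rec <- makePrediagnosis(sim$records, sim$cohort)
tc  <- tensorize(rec, sim$cohort, taxVariables(tax),
                 nBins = 12, binWidthMonths = 2)

te <- trainEval(tax, tc, "composite", strategy = "g1",
                config = trainConfig(nRepeats = 3, seed = 7))
te
#> composite model (g1) over 3 repeats: AUROC 0.968 [0.904, 1.031], AUPRC 0.970 [0.911, 1.029]

emb <- predictEmbeddings(te$fits[[1]]$model, tc)
gm  <- clusterEmbeddings(emb@level3, nComponents = 2, seed = 1)
totalEntropy(gm$assignments, labels = cohortLabels(tc))
#> [1] 0

sh <- layerShap(te$fits[[1]]$model, tc, backgroundSize = 20, seed = 1)
s3 <- sh$summary[sh$summary$layer == 3, ]
s3[order(-s3$mean_abs_shap), ]
#>    layer                   unit     parent mean_abs_shap       sd
#> 33     3   liver function group prediction      0.289702 0.031356
#> 34     3           kidney group prediction      0.108408 0.073891
#> 31     3 white blood cell group prediction      0.009166 0.006231
#> 35     3         diabetes group prediction      0.008961 0.007388
#> 32     3   red blood cell group prediction      0.005909 0.004645
```

The mean AUROC of 0.97 says the injected 0.15 SD/month liver-function drift
is easily detected; the zero total entropy says the two mixture components
separate cases from controls perfectly in the composite embedding space;
and the SHAP table attributes the prediction dominantly to the liver
function group — the composite the signal was injected into.

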