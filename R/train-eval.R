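#' Training protocol configuration
#'
#' Defaults follow the protocol this model family is evaluated under: 10
#' repeated experiments, each on a fresh stratified 80/20 train/test split,
#' trained up to 50 epochs with early stopping on the test loss (the split
#' protocol monitors the same held-out set it reports on; an optional
#' three-way split is available via `validationFraction`).
#'
#' @param nRepeats Number of repeated experiments (default 10).
#' @param testFraction Held-out fraction per repeat (default 0.2).
#' @param maxEpochs Epoch cap (default 50).
#' @param patience Epochs without monitored-loss improvement before stopping
#'   (default 5).
#' @param minEpochs Floor before the patience counter is armed (default 10);
#'   prevents aborting on the initial loss plateau, where minibatch noise can
#'   tick the monitored loss upward before training has escaped
#'   initialisation.
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize Minibatch size (default 32).
#' @param weightDecay L2 penalty coefficient on all weights (default 3e-3);
#'   curbs the memorisation of noise variables that small clinical cohorts
#'   invite.
#' @param validationFraction If positive, carve this fraction out of the
#'   training set and monitor early stopping there instead of on the test set
#'   (off by default, matching the stated protocol).
#' @param seed Integer seed; repeat r's split is a pure function of (seed, r).
#' @return A classed list of settings.
#' @export
trainConfig <- function(nRepeats = 10L, testFraction = 0.2, maxEpochs = 50L,
                        patience = 5L, minEpochs = 10L, learningRate = 1e-3,
                        batchSize = 32L, weightDecay = 3e-3,
                        validationFraction = 0, seed = 1L) {
  stopifnot(testFraction > 0, testFraction < 1, maxEpochs >= 1,
            learningRate > 0, weightDecay >= 0,
            validationFraction >= 0, validationFraction < 1)
  structure(list(nRepeats = as.integer(nRepeats), testFraction = testFraction,
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 minEpochs = as.integer(minEpochs),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 weightDecay = weightDecay,
                 validationFraction = validationFraction,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Fit a structured model by minibatch gradient descent with early stopping
#'
#' Minimises the mean negative log-likelihood with Adam, monitoring loss on
#' `(xMonitor, yMonitor)` after every epoch and restoring the best-epoch
#' weights on return, so the fitted model never has worse monitored loss than
#' the best epoch seen.
#'
#' @param model A [StructuredModel-class].
#' @param x Training array, patients x variables x bins.
#' @param y Integer labels (0 = control, 1 = case).
#' @param xMonitor,yMonitor Held-out data monitored for early stopping.
#' @param maxEpochs,patience,learningRate,batchSize,weightDecay See
#'   [trainConfig()].
#' @param shuffleSeed Seed for the per-epoch minibatch shuffle.
#' @return A list: `model` (best weights), `history` (per-epoch train and
#'   monitored loss), `epochsRun`, `bestEpoch`.
#' @export
fitModel <- function(model, x, y, xMonitor, yMonitor, maxEpochs = 50L,
                     patience = 5L, minEpochs = 10L, learningRate = 1e-3,
                     batchSize = 32L, weightDecay = 3e-3, shuffleSeed = 1L) {
  theta <- unlist(model@params, use.names = FALSE)
  mAd <- numeric(length(theta))
  vAd <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  N <- dim(x)[1L]
  bestLoss <- Inf
  bestTheta <- theta
  bestEpoch <- 0L
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     monitor_loss = numeric(0))
  set.seed(shuffleSeed)
  for (epoch in seq_len(maxEpochs)) {
    ord <- sample.int(N)
    starts <- seq(1L, N, by = batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + batchSize - 1L, N)]
      lg <- lossGrad(model, x[idx, , , drop = FALSE], y[idx])
      gflat <- unlist(lg$grads, use.names = FALSE) + weightDecay * theta
      step <- step + 1L
      mAd <- beta1 * mAd + (1 - beta1) * gflat
      vAd <- beta2 * vAd + (1 - beta2) * gflat^2
      mh <- mAd / (1 - beta1^step)
      vh <- vAd / (1 - beta2^step)
      theta <- theta - learningRate * mh / (sqrt(vh) + eps)
      model@params <- relistLike(theta, model@params)
    }
    trLoss <- meanLoss(model, x, y)
    moLoss <- meanLoss(model, xMonitor, yMonitor)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = trLoss,
                                   monitor_loss = moLoss))
    if (moLoss < bestLoss - 1e-9) {
      bestLoss <- moLoss
      bestTheta <- theta
      bestEpoch <- epoch
      bad <- 0L
    } else if (epoch > minEpochs) {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  model@params <- relistLike(bestTheta, model@params)
  list(model = model, history = hist, epochsRun = nrow(hist),
       bestEpoch = bestEpoch)
}

#' Area under the ROC curve by the rank (Mann-Whitney) method
#'
#' @param scores Numeric risk scores, higher = more case-like.
#' @param labels Integer/logical/factor labels; cases are `1`, `TRUE` or the
#'   level `"case"`.
#' @return AUROC in `[0, 1]`; ties handled by midranks.
#' @export
aurocScore <- function(scores, labels) {
  pos <- asCase(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function average precision: the mean, over positives, of the
#' precision at each positive's rank when scores are sorted decreasingly.
#'
#' @inheritParams aurocScore
#' @return AUPRC in `[0, 1]`.
#' @export
auprcScore <- function(scores, labels) {
  pos <- asCase(labels)
  stopifnot(any(pos), any(!pos))
  ord <- order(-scores)
  hit <- pos[ord]
  prec <- cumsum(hit) / seq_along(hit)
  mean(prec[hit])
}

asCase <- function(labels) {
  if (is.factor(labels) || is.character(labels)) as.character(labels) == "case"
  else as.logical(labels)
}

#' Train and evaluate a structured model with repeated splits
#'
#' Per repeat: a fresh stratified split (a pure function of the config seed
#' and the repeat number), a fresh seeded initialisation, gradient training on
#' the negative log-likelihood with early stopping, and AUROC/AUPRC on the
#' held-out set, scoring patients by the case log-probability.
#'
#' @param taxonomy A [Taxonomy-class].
#' @param tensorized A [TensorizedCohort-class].
#' @param level,strategy,hidden Passed to [buildModel()].
#' @param config A [trainConfig()].
#' @param keepFits Keep each repeat's fitted model and test indices (needed
#'   for early-detection sweeps and interpretability; default TRUE).
#' @return A list of class `evaluationResult`: `results` (per-repeat
#'   data.frame with auroc, auprc, epochs), `summary` (means with 95%
#'   normal-theory CIs), and `fits` when kept.
#' @export
trainEval <- function(taxonomy, tensorized, level, strategy = NULL,
                      hidden = 16L, config = trainConfig(), keepFits = TRUE) {
  labs <- cohortLabels(tensorized)
  stopifnot(nlevels(droplevels(labs)) == 2L)
  X <- gridValues(tensorized)
  y <- as.integer(labs == "case")
  res <- data.frame()
  fits <- list()
  for (r in seq_len(config$nRepeats)) {
    splitSeed <- stageSeed(config$seed, sprintf("split%d", r))
    testIdx <- stratifiedSplit(y, config$testFraction, splitSeed)
    trainIdx <- setdiff(seq_along(y), testIdx)
    monIdx <- testIdx
    if (config$validationFraction > 0) {
      vIdx <- trainIdx[stratifiedSplit(y[trainIdx],
                                       config$validationFraction,
                                       stageSeed(splitSeed, "val"))]
      trainIdx <- setdiff(trainIdx, vIdx)
      monIdx <- vIdx
    }
    model <- buildModel(taxonomy, level, strategy = strategy,
                        nBins = dim(X)[3L], hidden = hidden,
                        seed = stageSeed(config$seed, sprintf("init%d", r)))
    fit <- fitModel(model, X[trainIdx, , , drop = FALSE], y[trainIdx],
                    X[monIdx, , , drop = FALSE], y[monIdx],
                    maxEpochs = config$maxEpochs, patience = config$patience,
                    minEpochs = config$minEpochs,
                    learningRate = config$learningRate,
                    batchSize = config$batchSize,
                    weightDecay = config$weightDecay,
                    shuffleSeed = stageSeed(config$seed, sprintf("shuffle%d", r)))
    fw <- forwardInternal(fit$model, X[testIdx, , , drop = FALSE])
    score <- fw$logits[, "case"]
    res <- rbind(res, data.frame(
      repeat_id = r,
      auroc = aurocScore(score, y[testIdx]),
      auprc = auprcScore(score, y[testIdx]),
      epochs = fit$epochsRun))
    if (keepFits) fits[[r]] <- list(model = fit$model, testIdx = testIdx)
  }
  ci <- function(v) {
    se <- stats::sd(v) / sqrt(length(v))
    c(mean = mean(v), lo = mean(v) - 1.96 * se, hi = mean(v) + 1.96 * se)
  }
  structure(list(level = level, strategy = strategy, results = res,
                 summary = rbind(auroc = ci(res$auroc), auprc = ci(res$auprc)),
                 fits = if (keepFits) fits),
            class = "evaluationResult")
}

#' @export
print.evaluationResult <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s model%s over %d repeats: AUROC %.3f [%.3f, %.3f], AUPRC %.3f [%.3f, %.3f]\n",
              x$level,
              if (!is.null(x$strategy) && !is.na(x$strategy))
                paste0(" (", x$strategy, ")") else "",
              nrow(x$results),
              s["auroc", "mean"], s["auroc", "lo"], s["auroc", "hi"],
              s["auprc", "mean"], s["auprc", "lo"], s["auprc", "hi"]))
  invisible(x)
}

#' Early-detection sweep: evaluate a frozen model on censored inputs
#'
#' For each `k` in `months`, records are censored to those taken more than
#' `k` months before the index date, re-tensorized with the training scale,
#' and scored by the already-trained model without any retraining. Patients
#' whose record set empties become all-zero grids and are kept, per the
#' zero-imputation convention.
#'
#' @param fit A fitted [StructuredModel-class].
#' @param records,cohort The (pre-diagnosis) record and cohort tables.
#' @param months Censoring horizons in months (default `c(0, 3, 6, 12)`).
#' @param tensorized The training [TensorizedCohort-class] (supplies bins,
#'   bin width, variable order and scaling).
#' @param patients Optional patient subset to evaluate (e.g. a repeat's
#'   held-out split); default all.
#' @return data.frame (months, auroc, auprc, n_records).
#' @export
earlyDetectionSweep <- function(fit, records, cohort,
                                months = c(0, 3, 6, 12), tensorized,
                                patients = NULL) {
  vars <- taxVariables(tensorized)
  nBins <- dim(gridValues(tensorized))[3L]
  out <- data.frame()
  for (k in months) {
    rec <- censorAtMonths(records, cohort, k)
    tc <- suppressMessages(
      tensorize(rec, cohort, vars, nBins = nBins,
                binWidthMonths = tensorized@binWidthMonths,
                standardize = nrow(tensorized@scaling) > 0,
                scaling = if (nrow(tensorized@scaling)) tensorized@scaling))
    keep <- if (is.null(patients)) patientIds(tc)
            else intersect(patientIds(tc), patients)
    ix <- match(keep, patientIds(tc))
    fw <- forwardInternal(fit, gridValues(tc)[ix, , , drop = FALSE])
    y <- as.integer(cohortLabels(tc)[ix] == "case")
    out <- rbind(out, data.frame(months = k,
                                 auroc = aurocScore(fw$logits[, "case"], y),
                                 auprc = auprcScore(fw$logits[, "case"], y),
                                 n_records = nrow(rec)))
  }
  out
}
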