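#' Pipeline run configuration
#'
#' Assembles per-stage settings for [runPipeline()] with validated defaults.
#' Every stage's seed is derived deterministically from the global seed via
#' [stageSeed()], so re-running any stage in isolation is independent of
#' execution order. The defaults define the package's reference synthetic
#' study: 200 cases / 200 controls over a 60-month lookback, signal injected
#' into the liver function group at 0.15 SD/month, monthly bins over the most
#' recent 24 months, and all three model levels trained with the standard
#' 10-repeat protocol.
#'
#' @param simulate,prep,train,evaluate,entropy,explain,trends Named lists
#'   overriding stage defaults (see the implementation of each stage in
#'   [runPipeline()]).
#' @param seed Global integer seed.
#' @return A classed, validated nested list.
#' @export
pipelineConfig <- function(simulate = list(), prep = list(), train = list(),
                           evaluate = list(), entropy = list(),
                           explain = list(), trends = list(), seed = 1L) {
  defaults <- list(
    simulate = list(nCases = 200L, nControls = 300L,
                    lookbackMonths = 60, visitRate = 12, missingness = 0.7,
                    signalGroups = "liver function group",
                    signalStrategy = "g1", driftPerMonth = 0.15,
                    rampMonths = 24, noiseSd = 1,
                    controlReduction = 0.1),
    prep = list(nBins = 24L, binWidthMonths = 1, match = TRUE),
    train = list(levels = c("base", "combo", "composite"), strategy = "g1",
                 hidden = 16L, nRepeats = 10L, testFraction = 0.2,
                 maxEpochs = 50L, patience = 5L, learningRate = 1e-3,
                 batchSize = 32L),
    evaluate = list(months = c(0, 3, 6, 12)),
    entropy = list(nComponents = 2L),
    explain = list(backgroundSize = 50L, importanceRepeats = 10L),
    trends = list(anchors = c(0, 3, 6, 12), halfWindowMonths = 2)
  )
  user <- list(simulate = simulate, prep = prep, train = train,
               evaluate = evaluate, entropy = entropy, explain = explain,
               trends = trends)
  for (st in names(user)) {
    if (!is.list(user[[st]])) {
      stop(sprintf("config validation error: stage block '%s' must be a list", st))
    }
    bad <- setdiff(names(user[[st]]), names(defaults[[st]]))
    if (length(bad)) {
      stop(sprintf("config validation error: unknown setting '%s' in stage '%s'",
                   bad[1L], st))
    }
    defaults[[st]][names(user[[st]])] <- user[[st]]
  }
  defaults$seed <- as.integer(seed)
  structure(defaults, class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with optional stage blocks and a `seed`.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  seed <- doc$seed %||% 1L
  doc$seed <- NULL
  do.call(pipelineConfig, c(doc, list(seed = seed)))
}

#' Run the full pipeline: simulate through temporal trends
#'
#' Executes simulate -> prep -> train -> evaluate -> entropy -> explain ->
#' trends on the synthetic study defined by the configuration, optionally
#' writing stage outputs and a manifest to `outDir`. Any stage failure aborts
#' with the stage name; outputs of completed stages persist. The manifest
#' (config echo, stage seeds, output hashes and package version) makes any
#' derived figure regenerable from the manifest alone, and identical
#' configurations produce identical manifests.
#'
#' @param config A [pipelineConfig()] (or a YAML path accepted by
#'   [readPipelineConfig()]).
#' @param outDir Optional output directory for CSV/JSON stage outputs.
#' @return Invisibly, a list with `manifest` and every stage's in-memory
#'   results.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  requiredBlocks <- c("simulate", "prep", "train", "evaluate", "entropy",
                      "explain", "trends", "seed")
  missing <- setdiff(requiredBlocks, names(config))
  if (length(missing)) {
    stop(sprintf("config validation error: missing stage block '%s'", missing[1L]))
  }
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  tax <- syntheticTaxonomy()

  ## -- simulate
  results$simulate <- stage("simulate", function() {
    sc <- config$simulate
    cfg <- generatorConfig(nCases = sc$nCases, nControls = sc$nControls,
                           taxonomy = tax, lookbackMonths = sc$lookbackMonths,
                           visitRate = sc$visitRate,
                           missingness = sc$missingness,
                           signalGroups = sc$signalGroups,
                           signalStrategy = sc$signalStrategy,
                           driftPerMonth = sc$driftPerMonth,
                           rampMonths = sc$rampMonths, noiseSd = sc$noiseSd,
                           seed = stageSeed(config$seed, "simulate"))
    sim <- simulateCohort(cfg)
    shifted <- assignControlIndexDates(sim$records, sim$cohort,
                                       sc$controlReduction,
                                       lookbackMonths = sc$lookbackMonths,
                                       seed = stageSeed(config$seed, "index"))
    sim$records <- shifted$records
    sim$cohort <- shifted$cohort
    if (!is.null(outDir)) writeCohort(sim, file.path(outDir, "cohort"))
    sim
  })

  ## -- prep
  results$prep <- stage("prep", function() {
    sim <- results$simulate
    rec <- makePrediagnosis(sim$records, sim$cohort)
    cohort <- sim$cohort
    match <- NULL
    if (isTRUE(config$prep$match)) {
      match <- propensityMatch(cohort, seed = stageSeed(config$seed, "match"))
      keep <- cohort$label == "case" |
        cohort$patient_id %in% match$matchedControlIds
      cohort <- cohort[keep, , drop = FALSE]
      rec <- rec[rec$patient_id %in% cohort$patient_id, , drop = FALSE]
    }
    tc <- suppressMessages(
      tensorize(rec, cohort, taxVariables(tax),
                nBins = config$prep$nBins,
                binWidthMonths = config$prep$binWidthMonths))
    list(records = rec, cohort = cohort, tensorized = tc, match = match)
  })

  ## -- train
  results$train <- stage("train", function() {
    tr <- config$train
    cfg <- trainConfig(nRepeats = tr$nRepeats, testFraction = tr$testFraction,
                       maxEpochs = tr$maxEpochs, patience = tr$patience,
                       learningRate = tr$learningRate,
                       batchSize = tr$batchSize,
                       seed = stageSeed(config$seed, "train"))
    evals <- list()
    for (lvl in tr$levels) {
      evals[[lvl]] <- trainEval(tax, results$prep$tensorized, lvl,
                                strategy = if (lvl == "composite") tr$strategy,
                                hidden = tr$hidden, config = cfg)
    }
    if (!is.null(outDir)) {
      tidy <- do.call(rbind, lapply(names(evals), function(lvl) {
        cbind(model = lvl, evals[[lvl]]$results)
      }))
      utils::write.csv(tidy, file.path(outDir, "metrics.csv"),
                       row.names = FALSE)
    }
    evals
  })

  ## -- evaluate (early-detection sweep on the first repeat's held-out split)
  results$evaluate <- stage("evaluate", function() {
    lvl <- utils::tail(config$train$levels, 1L)
    fit1 <- results$train[[lvl]]$fits[[1L]]
    tc <- results$prep$tensorized
    sweep <- earlyDetectionSweep(fit1$model, results$prep$records,
                                 results$prep$cohort,
                                 months = config$evaluate$months,
                                 tensorized = tc,
                                 patients = patientIds(tc)[fit1$testIdx])
    if (!is.null(outDir)) {
      utils::write.csv(sweep, file.path(outDir, "early_detection.csv"),
                       row.names = FALSE)
    }
    sweep
  })

  ## -- entropy
  results$entropy <- stage("entropy", function() {
    tc <- results$prep$tensorized
    out <- data.frame()
    for (lvl in names(results$train)) {
      fit1 <- results$train[[lvl]]$fits[[1L]]
      emb <- predictEmbeddings(fit1$model, tc)
      E <- switch(lvl, base = emb@level1, combo = emb@level2,
                  composite = emb@level3)
      gm <- clusterEmbeddings(E, nComponents = config$entropy$nComponents,
                              seed = stageSeed(config$seed, "entropy"))
      out <- rbind(out, data.frame(
        model = lvl,
        entropy = totalEntropy(gm$assignments,
                               labels = cohortLabels(tc))))
    }
    if (!is.null(outDir)) {
      utils::write.csv(out, file.path(outDir, "entropy.csv"), row.names = FALSE)
    }
    out
  })

  ## -- explain
  results$explain <- stage("explain", function() {
    tc <- results$prep$tensorized
    deepest <- utils::tail(intersect(c("base", "combo", "composite"),
                                     names(results$train)), 1L)
    fitC <- results$train[[deepest]]$fits[[1L]]
    emb <- predictEmbeddings(fitC$model, tc)
    Efinal <- switch(deepest, base = emb@level1, combo = emb@level2,
                     composite = emb@level3)
    importance <- compositeImportance(Efinal, cohortLabels(tc),
                                      nRepeats = config$explain$importanceRepeats,
                                      seed = stageSeed(config$seed, "importance"))
    shap <- layerShap(fitC$model, tc,
                      backgroundSize = config$explain$backgroundSize,
                      seed = stageSeed(config$seed, "shap"))
    if (!is.null(outDir)) {
      utils::write.csv(importance, file.path(outDir, "importance.csv"),
                       row.names = FALSE)
      utils::write.csv(shap$summary, file.path(outDir, "layer_shap.csv"),
                       row.names = FALSE)
    }
    list(importance = importance, shap = shap)
  })

  ## -- trends
  results$trends <- stage("trends", function() {
    tr <- temporalTrends(results$prep$records, results$prep$cohort,
                         results$simulate$normalRanges,
                         anchors = config$trends$anchors,
                         halfWindowMonths = config$trends$halfWindowMonths)
    if (!is.null(outDir)) {
      utils::write.csv(tr$trends, file.path(outDir, "trends.csv"),
                       row.names = FALSE)
    }
    tr
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("strudem")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(c("simulate", "index", "match", "train", "entropy",
               "importance", "shap"),
             function(s) stageSeed(config$seed, s)),
      c("simulate", "index", "match", "train", "entropy", "importance",
        "shap")),
    config = unclass(config),
    n_records = nrow(results$simulate$records),
    auroc_mean = as.list(vapply(results$train, function(e)
      unname(e$summary["auroc", "mean"]), numeric(1L)))
  )
  if (!is.null(outDir)) {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(manifest = manifest, results = results))
}
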