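#' Shapley values of a vector-valued model over a background sample
#'
#' Interventional Shapley attribution of `f(x)` for each row of `x`: the
#' value of a coalition S is the mean of `f` over the background rows with
#' the S columns replaced by the explained row's values. Small problems
#' (`p <= exactLimit`) are solved by exact subset enumeration; larger ones by
#' permutation sampling (mean of marginal contributions along seeded random
#' feature orders). Both estimators satisfy the additivity (efficiency)
#' property exactly by construction:
#' `rowSums(phi) + base = f(x)` up to floating point.
#'
#' @param f Function taking a numeric matrix (rows = instances, cols =
#'   features) and returning a numeric vector of outputs.
#' @param x Numeric matrix of instances to explain.
#' @param background Numeric matrix of background instances (same columns).
#' @param exactLimit Feature count up to which exact enumeration is used
#'   (default 12).
#' @param nPermutations Permutations for the sampling estimator (default 64).
#' @param seed Integer seed for the sampling estimator.
#' @return A list: `phi` (instances x features), `base` (scalar
#'   `mean(f(background))`), `fx` (`f(x)`), `method`.
#' @export
shapleyValues <- function(f, x, background, exactLimit = 12L,
                          nPermutations = 64L, seed = 1L) {
  x <- as.matrix(x)
  background <- as.matrix(background)
  p <- ncol(x)
  stopifnot(ncol(background) == p, nrow(background) >= 1L)
  N <- nrow(x)
  B <- nrow(background)
  Xrep <- x[rep(seq_len(N), each = B), , drop = FALSE]
  Brep <- background[rep(seq_len(B), N), , drop = FALSE]
  vOf <- function(cols) { # value of coalition `cols` for every instance
    M <- Brep
    if (length(cols)) M[, cols] <- Xrep[, cols, drop = FALSE]
    colMeans(matrix(f(M), nrow = B))
  }
  base <- mean(f(background))
  fx <- f(x)
  if (p <= exactLimit) {
    nS <- bitwShiftL(1L, p)
    v <- matrix(0, nS, N)
    sizes <- integer(nS)
    for (s in seq_len(nS) - 1L) {
      cols <- which(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      sizes[s + 1L] <- length(cols)
      v[s + 1L, ] <- if (s == 0L) base else vOf(cols)
    }
    wt <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
                lfactorial(p))
    phi <- matrix(0, N, p)
    for (i in seq_len(p)) {
      bit <- bitwShiftL(1L, i - 1L)
      without <- which(bitwAnd(seq_len(nS) - 1L, bit) == 0L)
      for (s in without) {
        phi[, i] <- phi[, i] + wt[sizes[s] + 1L] * (v[s + bit, ] - v[s, ])
      }
    }
    method <- "exact"
  } else {
    set.seed(seed)
    phi <- matrix(0, N, p)
    for (perm in seq_len(nPermutations)) {
      ord <- sample.int(p)
      vPrev <- rep(base, N)
      cols <- integer(0)
      for (j in seq_len(p)) {
        cols <- c(cols, ord[j])
        vCur <- if (j == p) fx else vOf(cols)
        phi[, ord[j]] <- phi[, ord[j]] + (vCur - vPrev)
        vPrev <- vCur
      }
    }
    phi <- phi / nPermutations
    method <- "permutation"
  }
  colnames(phi) <- colnames(x)
  list(phi = phi, base = base, fx = fx, method = method)
}

#' Per-layer Shapley attribution of a structured model
#'
#' Explains the case log-probability at every hierarchy level of a trained
#' model: at the deepest level the prediction head is explained as a function
#' of the final embeddings; at shallower levels the explained function is the
#' model's own downstream layers applied to that level's embeddings. The
#' background is a seeded sample of the cohort's own embeddings. Reports the
#' mean absolute Shapley value per unit with its SD over patients, plus each
#' unit's parent in the next grouping layer (the cross-layer linkage used in
#' linked bar charts).
#'
#' @param model A trained [StructuredModel-class].
#' @param tensorized A [TensorizedCohort-class] (typically the cohort or a
#'   held-out split).
#' @param backgroundSize Background sample cap (default 50; capped at the
#'   cohort size with a warning).
#' @param seed Integer seed.
#' @param exactLimit,nPermutations Passed to [shapleyValues()].
#' @return A list of class `layerShapReport`: `summary` (data.frame layer,
#'   unit, parent, mean_abs_shap, sd) and `detail` (per layer: `phi`, `base`,
#'   `fx`).
#' @export
layerShap <- function(model, tensorized, backgroundSize = 50L, seed = 1L,
                      exactLimit = 12L, nPermutations = 64L) {
  emb <- predictEmbeddings(model, tensorized)
  n <- nrow(emb@logits)
  if (backgroundSize > n) {
    warning(sprintf("background (%d) larger than cohort (%d); capped",
                    backgroundSize, n))
    backgroundSize <- n
  }
  set.seed(seed)
  bgIdx <- sample.int(n, backgroundSize)

  tax <- model@taxonomy
  cm <- comboMap(tax)
  sm <- if (!is.na(model@strategy)) strategyMap(tax, model@strategy)
  levelsAvail <- list(
    list(layer = 1L, E = emb@level1,
         parent = if (model@level != "base") unname(cm[colnames(emb@level1)])
                  else rep(NA_character_, ncol(emb@level1))),
    if (ncol(emb@level2))
      list(layer = 2L, E = emb@level2,
           parent = if (!is.null(sm)) unname(sm[colnames(emb@level2)])
                    else rep(NA_character_, ncol(emb@level2))),
    if (ncol(emb@level3))
      list(layer = 3L, E = emb@level3,
           parent = rep("prediction", ncol(emb@level3)))
  )
  levelsAvail <- Filter(Negate(is.null), levelsAvail)

  summary <- data.frame()
  detail <- list()
  for (lv in levelsAvail) {
    fLv <- function(E) forwardFromLevel(model, lv$layer, E)[, 2L]
    sv <- shapleyValues(fLv, lv$E, lv$E[bgIdx, , drop = FALSE],
                        exactLimit = exactLimit,
                        nPermutations = nPermutations,
                        seed = stageSeed(seed, sprintf("layer%d", lv$layer)))
    summary <- rbind(summary, data.frame(
      layer = lv$layer, unit = colnames(lv$E), parent = lv$parent,
      mean_abs_shap = colMeans(abs(sv$phi)),
      sd = apply(abs(sv$phi), 2L, stats::sd), row.names = NULL))
    detail[[sprintf("layer%d", lv$layer)]] <- sv
  }
  structure(list(summary = summary, detail = detail),
            class = "layerShapReport")
}

#' Composite-index feature importance under four classifiers
#'
#' Fits logistic regression, a decision tree, a random forest and gradient
#' boosting to the composite embeddings and reports normalised importance
#' scores: absolute standardized coefficients for the logistic model and
#' split-criterion (impurity) reduction scores for the tree family. Each
#' method is refit on seeded stratified 80% subsamples for `nRepeats`
#' repeats; per-repeat scores are normalised to sum to one, then averaged
#' (and re-normalised) with SDs.
#'
#' @param embeddings Numeric matrix, patients x composites (column names are
#'   the composite ids).
#' @param labels Case/control labels.
#' @param nRepeats Seeded refits (default 10).
#' @param seed Integer seed.
#' @param methods Subset of `c("logistic_regression", "decision_tree",
#'   "random_forest", "xgboost")`.
#' @return data.frame (method, composite, importance, sd); importances are
#'   nonnegative and sum to 1 within each method.
#' @export
compositeImportance <- function(embeddings, labels, nRepeats = 10L, seed = 1L,
                                methods = c("logistic_regression",
                                            "decision_tree", "random_forest",
                                            "xgboost")) {
  E <- as.matrix(embeddings)
  comps <- colnames(E) %||% sprintf("x%d", seq_len(ncol(E)))
  colnames(E) <- make.names(comps) # model-safe names
  y <- factor(asCase(labels), levels = c(FALSE, TRUE),
              labels = c("control", "case"))
  const <- apply(E, 2L, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("constant embedding column(s) get zero importance: %s",
                    paste(comps[const], collapse = ", ")))
  }
  oneFit <- function(method, idx, s) {
    Xi <- E[idx, , drop = FALSE]
    yi <- y[idx]
    sc <- stats::setNames(numeric(ncol(E)), colnames(E))
    if (method == "logistic_regression") {
      Xs <- scale(Xi)
      Xs[, !is.finite(colSums(Xs))] <- 0
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Xs),
                                             as.integer(yi == "case"),
                                             family = stats::binomial()))
      co <- fit$coefficients[-1L]
      co[!is.finite(co)] <- 0
      sc[] <- abs(co)
    } else if (method == "decision_tree") {
      df <- data.frame(y = yi, Xi)
      fit <- rpart::rpart(y ~ ., df, method = "class",
                          control = rpart::rpart.control(cp = 0.001))
      vi <- fit$variable.importance
      if (!is.null(vi)) sc[names(vi)] <- vi
    } else if (method == "random_forest") {
      set.seed(s)
      fit <- randomForest::randomForest(Xi, yi, ntree = 200L)
      sc[rownames(fit$importance)] <- fit$importance[, "MeanDecreaseGini"]
    } else if (method == "xgboost") {
      fit <- xgboost::xgboost(Xi, yi, nrounds = 50L, max_depth = 3L,
                              learning_rate = 0.3, nthreads = 1L,
                              verbosity = 0L)
      imp <- xgboost::xgb.importance(model = fit)
      sc[imp$Feature] <- imp$Gain
    }
    sc[const] <- 0
    if (sum(sc) > 0) sc / sum(sc) else sc + 1 / length(sc)
  }
  out <- data.frame()
  for (method in methods) {
    reps <- matrix(0, nRepeats, ncol(E))
    for (r in seq_len(nRepeats)) {
      s <- stageSeed(seed, sprintf("%s%d", method, r))
      set.seed(s)
      idx <- setdiff(seq_along(y), stratifiedSplit(y, 0.2, s))
      reps[r, ] <- oneFit(method, idx, s)
    }
    m <- colMeans(reps)
    out <- rbind(out, data.frame(method = method, composite = comps,
                                 importance = m / sum(m),
                                 sd = apply(reps, 2L, stats::sd),
                                 row.names = NULL))
  }
  out
}

#' Accumulate base-model variable attributions into composite indices
#'
#' Sums per-variable mean-absolute Shapley values over each composite of a
#' strategy (via the variable -> combo -> composite closure). Intended for
#' comparison against the composite model's own level-3 report; attribution
#' is architecture-dependent, so the two generally differ. The grand sum of
#' the inputs is conserved exactly.
#'
#' @param variableShap Named numeric vector, variable -> mean absolute
#'   Shapley value (e.g. from a base-model [layerShap()]).
#' @param taxonomy A [Taxonomy-class].
#' @param strategy Strategy name.
#' @return Named numeric vector, composite -> accumulated value.
#' @export
accumulatedShap <- function(variableShap, taxonomy, strategy) {
  sm <- strategyMap(taxonomy, strategy)
  cm <- comboMap(taxonomy)
  vars <- names(variableShap)
  missing <- vars[!vars %in% names(cm)]
  if (length(missing)) {
    stop(sprintf("variable missing from the strategy closure: %s", missing[1L]))
  }
  comp <- unname(sm[cm[vars]])
  out <- tapply(variableShap, factor(comp, levels = composites(taxonomy, strategy)),
                sum)
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), names(out))
}

#' Linked bar chart of per-layer Shapley attributions
#'
#' Renders the layered mean-|SHAP| report as horizontal bars per layer,
#' coloured by each unit's top-level parent so cross-layer affiliations can
#' be followed visually. Requires ggplot2.
#'
#' @param report A `layerShapReport` from [layerShap()].
#' @param taxonomy The model's taxonomy (for resolving top-level parents).
#' @param strategy Strategy name used by the model.
#' @return A ggplot object.
#' @export
plotLayerShap <- function(report, taxonomy, strategy) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotLayerShap requires the ggplot2 package")
  }
  s <- report$summary
  sm <- strategyMap(taxonomy, strategy)
  cm <- comboMap(taxonomy)
  s$composite <- ifelse(s$layer == 1L, unname(sm[cm[s$unit]]),
                        ifelse(s$layer == 2L, unname(sm[s$unit]), s$unit))
  s$unit <- stats::reorder(paste(s$layer, s$unit, sep = ": "),
                           s$mean_abs_shap)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean_abs_shap, y = .data$unit,
                                  fill = .data$composite)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(xmin = pmax(.data$mean_abs_shap - .data$sd, 0),
                                        xmax = .data$mean_abs_shap + .data$sd),
                           width = 0.3) +
    ggplot2::facet_wrap(~layer, scales = "free_y") +
    ggplot2::labs(x = "mean |SHAP|", y = NULL, fill = "composite")
}
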