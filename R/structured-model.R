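#' Build a structured deep embedding model
#'
#' Constructs the hierarchy-constrained network: every level-1 variable gets
#' an independent two-layer perceptron (`nBins -> hidden -> 1`, tanh hidden,
#' linear output) over its own binned sequence only; every combo (and, at the
#' composite level, every composite) gets an independent `members -> 1` linear
#' map followed by tanh. Because each sub-network is built only over its
#' members, cross-group connections are structurally absent: the gradient of
#' any embedding with respect to a non-member input variable is identically
#' zero. The prediction layer is a single linear map from the final embedding
#' vector to two outputs under log-softmax.
#'
#' @param taxonomy A validated [Taxonomy-class].
#' @param level `"base"`, `"combo"` or `"composite"`.
#' @param strategy Grouping-strategy name; required when `level = "composite"`.
#' @param nBins Number of input time bins per variable.
#' @param hidden Hidden width of each per-variable sub-network (default 16).
#' @param seed Integer initialisation seed; same spec + seed gives identical
#'   initial weights.
#' @return A [StructuredModel-class].
#' @examples
#' tax <- syntheticTaxonomy()
#' m <- buildModel(tax, "composite", strategy = "g1", nBins = 12)
#' embeddingWidths(m)
#' @export
buildModel <- function(taxonomy, level = c("base", "combo", "composite"),
                       strategy = NULL, nBins = 60L, hidden = 16L, seed = 1L) {
  level <- match.arg(level)
  methods::validObject(taxonomy)
  if (level == "composite") {
    if (is.null(strategy)) {
      stop("configuration error: a composite model requires a grouping strategy")
    }
    strategyMap(taxonomy, strategy) # errors if unknown
  } else {
    strategy <- NA_character_
  }
  V <- length(taxVariables(taxonomy))
  H <- as.integer(hidden)
  nBins <- as.integer(nBins)
  set.seed(seed)
  params <- list(var = list(
    W1 = array(stats::rnorm(nBins * H * V, 0, 1 / sqrt(nBins)),
               dim = c(nBins, H, V)),
    b1 = matrix(0, H, V),
    W2 = matrix(stats::rnorm(H * V, 0, 1 / sqrt(H)), H, V),
    b2 = numeric(V)
  ))
  mem <- modelMembersFor(taxonomy, level, strategy)
  ## group layers start at mean pooling plus noise: each group embedding is
  ## initially a smooth average of its members, which keeps early gradients
  ## flowing evenly instead of depending on a random (possibly cancelling)
  ## member mix
  groupInit <- function(members) list(
    w = lapply(members, function(ix)
      1 / length(ix) + stats::rnorm(length(ix), 0, 0.1 / sqrt(length(ix)))),
    b = numeric(length(members))
  )
  if (level %in% c("combo", "composite")) params$combo <- groupInit(mem$combo)
  if (level == "composite") params$composite <- groupInit(mem$composite)
  d <- switch(level, base = V, combo = length(mem$combo),
              composite = length(mem$composite))
  params$head <- list(W = matrix(stats::rnorm(d * 2, 0, 1 / sqrt(d)), d, 2),
                      b = numeric(2))
  new("StructuredModel", level = level, strategy = strategy,
      taxonomy = taxonomy, nBins = nBins, hidden = H, params = params,
      seed = as.integer(seed))
}

## member index lists for the grouping layers
modelMembersFor <- function(taxonomy, level, strategy) {
  vars <- taxVariables(taxonomy)
  out <- list()
  if (level %in% c("combo", "composite")) {
    combos <- taxCombos(taxonomy)
    cm <- comboMap(taxonomy)
    out$combo <- lapply(combos, function(cb) which(unname(cm[vars]) == cb))
    names(out$combo) <- combos
    if (level == "composite") {
      sm <- strategyMap(taxonomy, strategy)
      comps <- composites(taxonomy, strategy)
      out$composite <- lapply(comps, function(cp)
        which(unname(sm[combos]) == cp))
      names(out$composite) <- comps
    }
  }
  out
}

modelMembers <- function(model) {
  modelMembersFor(model@taxonomy, model@level,
                  if (is.na(model@strategy)) NULL else model@strategy)
}

#' @rdname accessors
#' @export
setMethod("embeddingWidths", "StructuredModel", function(x) {
  mem <- modelMembers(x)
  w <- c(level1 = length(taxVariables(x@taxonomy)))
  if (!is.null(mem$combo)) w <- c(w, level2 = length(mem$combo))
  if (!is.null(mem$composite)) w <- c(w, level3 = length(mem$composite))
  w
})

#' @rdname accessors
#' @export
setMethod("finalWidth", "StructuredModel", function(x) {
  w <- embeddingWidths(x)
  unname(w[length(w)])
})

#' @rdname accessors
#' @export
setMethod("countParams", "StructuredModel", function(x) {
  length(unlist(x@params, use.names = FALSE))
})

## ---- forward pass ---------------------------------------------------------

## X: N x V x nBins array. Returns embeddings, logits, and caches if asked.
forwardInternal <- function(model, X, cache = FALSE) {
  p <- model@params
  mem <- modelMembers(model)
  N <- dim(X)[1L]
  V <- dim(X)[2L]
  H <- model@hidden
  E1 <- matrix(0, N, V)
  Hs <- if (cache) vector("list", V) else NULL
  for (v in seq_len(V)) {
    Xv <- matrix(X[, v, ], ncol = model@nBins)
    Hv <- tanh(Xv %*% p$var$W1[, , v] +
                 matrix(p$var$b1[, v], N, H, byrow = TRUE))
    E1[, v] <- Hv %*% p$var$W2[, v] + p$var$b2[v]
    if (cache) Hs[[v]] <- Hv
  }
  E2 <- matrix(0, N, 0)
  E3 <- matrix(0, N, 0)
  if (!is.null(p$combo)) {
    E2 <- groupForward(E1, mem$combo, p$combo)
    colnames(E2) <- names(mem$combo)
  }
  if (!is.null(p$composite)) {
    E3 <- groupForward(E2, mem$composite, p$composite)
    colnames(E3) <- names(mem$composite)
  }
  Ef <- switch(model@level, base = E1, combo = E2, composite = E3)
  Z <- Ef %*% p$head$W + matrix(p$head$b, N, 2, byrow = TRUE)
  logp <- Z - rowLogSumExp(Z)
  colnames(E1) <- taxVariables(model@taxonomy)
  colnames(logp) <- c("control", "case")
  list(E1 = E1, E2 = E2, E3 = E3, logits = logp, H = Hs)
}

groupForward <- function(Ein, members, gp) {
  N <- nrow(Ein)
  out <- matrix(0, N, length(members))
  for (k in seq_along(members)) {
    out[, k] <- tanh(Ein[, members[[k]], drop = FALSE] %*% gp$w[[k]] + gp$b[k])
  }
  out
}

## run the network from a given level's embeddings to the log-probabilities;
## used by the per-layer Shapley explanations.
forwardFromLevel <- function(model, level, E) {
  p <- model@params
  mem <- modelMembers(model)
  lv <- level
  Ecur <- E
  if (lv == 1L && !is.null(p$combo)) {
    Ecur <- groupForward(Ecur, mem$combo, p$combo)
    lv <- 2L
  }
  if (lv == 2L && !is.null(p$composite)) {
    Ecur <- groupForward(Ecur, mem$composite, p$composite)
    lv <- 3L
  }
  Z <- Ecur %*% p$head$W + matrix(p$head$b, nrow(Ecur), 2, byrow = TRUE)
  Z - rowLogSumExp(Z)
}

#' Compute all intermediate embeddings and logits for a cohort
#'
#' Deterministic at inference (the network has no stochastic layers).
#'
#' @param model A [StructuredModel-class].
#' @param tensorized A [TensorizedCohort-class] whose variables are ordered
#'   exactly as in the model's taxonomy.
#' @return An [EmbeddingOutputs-class].
#' @export
predictEmbeddings <- function(model, tensorized) {
  X <- gridValues(tensorized)
  vars <- taxVariables(model@taxonomy)
  if (dim(X)[2L] != length(vars) ||
      !identical(dimnames(X)[[2L]], vars)) {
    stop(sprintf("shape error on the variable axis: expected %d variables ordered as the taxonomy",
                 length(vars)))
  }
  if (dim(X)[3L] != model@nBins) {
    stop(sprintf("shape error on the bin axis: model expects %d bins, got %d",
                 model@nBins, dim(X)[3L]))
  }
  fw <- forwardInternal(model, X)
  out <- new("EmbeddingOutputs", level1 = fw$E1, level2 = fw$E2,
             level3 = fw$E3, logits = fw$logits)
  rownames(out@logits) <- patientIds(tensorized)
  out
}

## ---- loss and gradients ---------------------------------------------------

## y: integer 0 (control) / 1 (case). Returns mean NLL and gradient container
## shaped like model@params.
lossGrad <- function(model, X, y) {
  p <- model@params
  mem <- modelMembers(model)
  N <- dim(X)[1L]
  V <- dim(X)[2L]
  fw <- forwardInternal(model, X, cache = TRUE)
  loss <- -mean(fw$logits[cbind(seq_len(N), y + 1L)])

  g <- zeroLike(p)
  dZ <- exp(fw$logits)
  dZ[cbind(seq_len(N), y + 1L)] <- dZ[cbind(seq_len(N), y + 1L)] - 1
  dZ <- dZ / N
  Ef <- switch(model@level, base = fw$E1, combo = fw$E2, composite = fw$E3)
  g$head$W <- crossprod(Ef, dZ)
  g$head$b <- colSums(dZ)
  dEf <- dZ %*% t(p$head$W)

  dE2 <- NULL
  dE1 <- NULL
  if (model@level == "composite") {
    dE2 <- matrix(0, N, ncol(fw$E2))
    for (k in seq_along(mem$composite)) {
      dz <- dEf[, k] * (1 - fw$E3[, k]^2)
      ix <- mem$composite[[k]]
      g$composite$w[[k]] <- drop(crossprod(fw$E2[, ix, drop = FALSE], dz))
      g$composite$b[k] <- sum(dz)
      dE2[, ix] <- dE2[, ix] + outer(dz, p$composite$w[[k]])
    }
  } else if (model@level == "combo") {
    dE2 <- dEf
  }
  if (!is.null(dE2)) {
    dE1 <- matrix(0, N, V)
    for (k in seq_along(mem$combo)) {
      dz <- dE2[, k] * (1 - fw$E2[, k]^2)
      ix <- mem$combo[[k]]
      g$combo$w[[k]] <- drop(crossprod(fw$E1[, ix, drop = FALSE], dz))
      g$combo$b[k] <- sum(dz)
      dE1[, ix] <- dE1[, ix] + outer(dz, p$combo$w[[k]])
    }
  } else {
    dE1 <- dEf
  }
  for (v in seq_len(V)) {
    de1 <- dE1[, v]
    Hv <- fw$H[[v]]
    g$var$W2[, v] <- crossprod(Hv, de1)
    g$var$b2[v] <- sum(de1)
    dH <- outer(de1, p$var$W2[, v]) * (1 - Hv^2)
    Xv <- matrix(X[, v, ], ncol = model@nBins)
    g$var$W1[, , v] <- crossprod(Xv, dH)
    g$var$b1[, v] <- colSums(dH)
  }
  list(loss = loss, grads = g)
}

## restore a flat parameter vector into the nested shape of `skel`
relistLike <- function(vec, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) {
      lapply(s, rec)
    } else {
      n <- length(s)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      attributes(out) <- attributes(s)
      out
    }
  }
  rec(skel)
}

meanLoss <- function(model, X, y) {
  fw <- forwardInternal(model, X)
  -mean(fw$logits[cbind(seq_len(dim(X)[1L]), y + 1L)])
}
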