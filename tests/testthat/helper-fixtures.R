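## Small shared fixtures, all built in code.

## three variables in two combos, one strategy with two composites
tinyTaxonomy <- function() {
  Taxonomy(c(a1 = "cA", a2 = "cA", b1 = "cB"),
           list(g = c(cA = "compA", cB = "compB")))
}

## a memoised small signal-bearing cohort used by several files
.fixtureCache <- new.env(parent = emptyenv())

smallSim <- function(seed = 11L, nCases = 60L, nControls = 60L,
                     drift = 0.15) {
  key <- sprintf("sim_%d_%d_%d_%s", seed, nCases, nControls, drift)
  if (is.null(.fixtureCache[[key]])) {
    cfg <- generatorConfig(nCases = nCases, nControls = nControls,
                           taxonomy = syntheticTaxonomy(),
                           lookbackMonths = 24,
                           signalGroups = if (drift != 0) "liver function group"
                                          else character(0),
                           driftPerMonth = drift, seed = seed)
    .fixtureCache[[key]] <- simulateCohort(cfg)
  }
  .fixtureCache[[key]]
}

smallTensorized <- function(seed = 11L) {
  key <- sprintf("tc_%d", seed)
  if (is.null(.fixtureCache[[key]])) {
    sim <- smallSim(seed)
    rec <- makePrediagnosis(sim$records, sim$cohort)
    .fixtureCache[[key]] <- suppressMessages(
      tensorize(rec, sim$cohort, taxVariables(syntheticTaxonomy()),
                nBins = 12, binWidthMonths = 2))
  }
  .fixtureCache[[key]]
}

## a quick trained composite fit on the small cohort
smallCompositeFit <- function(seed = 11L) {
  key <- sprintf("fit_%d", seed)
  if (is.null(.fixtureCache[[key]])) {
    tc <- smallTensorized(seed)
    te <- trainEval(syntheticTaxonomy(), tc, "composite", strategy = "g1",
                    config = trainConfig(nRepeats = 2L, seed = seed))
    .fixtureCache[[key]] <- list(fit = te$fits[[1L]], tc = tc, eval = te)
  }
  .fixtureCache[[key]]
}

## hand-rolled union-find, the independent oracle for correlation grouping
unionFindGroups <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

## random cluster-by-class count tables for entropy oracles
randomContingency <- function(seed) {
  set.seed(seed)
  k <- sample(2:6, 1)
  j <- sample(2:4, 1)
  counts <- matrix(stats::rpois(k * j, 6), k, j)
  counts[rowSums(counts) == 0, 1] <- 1L
  counts
}

## independent brute-force total entropy by direct double summation
bruteEntropy <- function(counts) {
  N <- sum(counts)
  total <- 0
  for (i in seq_len(nrow(counts))) {
    ni <- sum(counts[i, ])
    for (j in seq_len(ncol(counts))) {
      p <- counts[i, j] / ni
      if (p > 0) total <- total + p * log(p) * (ni / N)
    }
  }
  -total
}
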