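#' Days per month used for day/month conversions
#'
#' All conversions between day-resolution record times and month-resolution
#' windows use a fixed month length of 30.4375 days (365.25 / 12), removing
#' calendar ambiguity.
#'
#' @format A numeric scalar.
#' @export
DAYS_PER_MONTH <- 30.4375

#' Derive a stage seed from a global seed
#'
#' Stage seeds are a pure function of the global seed and the stage name, so
#' re-running one stage in isolation reproduces exactly what the full pipeline
#' would have done, independent of execution order.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

## row-wise log-sum-exp, numerically stable
rowLogSumExp <- function(z) {
  m <- apply(z, 1L, max)
  m + log(rowSums(exp(z - m)))
}

## recursive map over a nested list of numeric arrays (parameter containers)
mapParams <- function(f, x, ...) {
  if (is.list(x)) {
    extra <- lapply(list(...), function(e) e)
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) {
      args <- lapply(extra, `[[`, i)
      out[[i]] <- do.call(mapParams, c(list(f, x[[i]]), args))
    }
    out
  } else {
    f(x, ...)
  }
}

## zero container with the same shape as params
zeroLike <- function(params) mapParams(function(p) p * 0, params)

## stratified split of indices: pure function of (labels, fraction, seed)
stratifiedSplit <- function(labels, testFraction, seed) {
  stopifnot(testFraction > 0, testFraction < 1)
  set.seed(seed)
  test <- integer(0)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    nTest <- max(1L, round(length(idx) * testFraction))
    nTest <- min(nTest, length(idx) - 1L)
    test <- c(test, sample(idx, nTest))
  }
  sort(test)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
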