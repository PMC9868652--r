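#' Restrict records to strictly pre-diagnosis measurements
#'
#' Removes every measurement obtained at or after the patient's index
#' (diagnosis) date, i.e. keeps records with `t < 0` strictly. Input order is
#' preserved and the operation is idempotent.
#'
#' @param records data.frame (patient_id, variable_id, t, value).
#' @param cohort data.frame with one row per patient; every record's patient
#'   must appear here.
#' @return The filtered records.
#' @export
makePrediagnosis <- function(records, cohort) {
  unknown <- setdiff(records$patient_id, cohort$patient_id)
  if (length(unknown)) {
    stop(sprintf("record with unknown patient: %s", unknown[1L]))
  }
  out <- records[records$t < 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Censor records for early-detection evaluation
#'
#' Keeps only measurements taken more than `k` months before the index date
#' (strict inequality), using the fixed month length [DAYS_PER_MONTH]. With
#' `k = 0` this coincides with [makePrediagnosis()].
#'
#' @inheritParams makePrediagnosis
#' @param k Nonnegative number of months.
#' @return The filtered records.
#' @export
censorAtMonths <- function(records, cohort, k) {
  if (k < 0) stop("k must be nonnegative")
  unknown <- setdiff(records$patient_id, cohort$patient_id)
  if (length(unknown)) {
    stop(sprintf("record with unknown patient: %s", unknown[1L]))
  }
  out <- records[records$t < -k * DAYS_PER_MONTH, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin pre-diagnosis records into a fixed-length patient x variable grid
#'
#' Bin `b` (1-based, most recent first) covers the interval
#' `[-b w, -(b-1) w)` months before the index date; the bin value is the mean
#' of the measurements falling in it and empty bins are exactly 0 (the
#' zero-imputation convention). Values are standardized per variable (using
#' the mean/SD of the retained raw measurements, or a supplied scaling) before
#' binning, so 0 also equals the variable mean on the model's input scale.
#' Records at or after the index, or beyond the lookback window, are dropped
#' with a logged count.
#'
#' @inheritParams makePrediagnosis
#' @param variables Ordered variable ids for the grid columns (e.g.
#'   `taxVariables(taxonomy)`); variables never measured still get all-zero
#'   columns.
#' @param nBins Number of bins (default 60).
#' @param binWidthMonths Width of each bin in months (default 1).
#' @param standardize Standardize per variable (default TRUE).
#' @param scaling Optional data.frame (variable_id, center, scale) from a
#'   previous tensorization, so evaluation grids reuse the training scale.
#' @return A [TensorizedCohort-class].
#' @export
tensorize <- function(records, cohort, variables, nBins = 60L,
                      binWidthMonths = 1, standardize = TRUE, scaling = NULL) {
  stopifnot(nBins >= 1L)
  unknown <- setdiff(records$patient_id, cohort$patient_id)
  if (length(unknown)) {
    stop(sprintf("record with unknown patient: %s", unknown[1L]))
  }
  badVar <- setdiff(records$variable_id, variables)
  if (length(badVar)) {
    stop(sprintf("record variable not in the requested grid: %s", badVar[1L]))
  }
  patients <- cohort$patient_id
  nP <- length(patients)
  nV <- length(variables)

  m <- -records$t / DAYS_PER_MONTH           # months before index, > 0 pre-dx
  b <- ceiling(m / binWidthMonths)           # bin b covers [-bw, -(b-1)w) in
                                             # t-months; early edge closed
  postIdx <- records$t >= 0
  oldIdx <- !postIdx & b > nBins
  keep <- !postIdx & !oldIdx
  dropped <- c(post_index = sum(postIdx), beyond_window = sum(oldIdx))
  if (sum(dropped) > 0) {
    message(sprintf("tensorize: dropped %d post-index and %d beyond-window records",
                    dropped[["post_index"]], dropped[["beyond_window"]]))
  }
  rec <- records[keep, , drop = FALSE]
  b <- b[keep]
  i <- match(rec$patient_id, patients)
  j <- match(rec$variable_id, variables)

  val <- rec$value
  if (standardize) {
    if (is.null(scaling)) {
      center <- tapply(val, factor(rec$variable_id, levels = variables), mean)
      scl <- tapply(val, factor(rec$variable_id, levels = variables), stats::sd)
      center[is.na(center)] <- 0
      scl[is.na(scl) | scl == 0] <- 1
      scaling <- data.frame(variable_id = variables,
                            center = as.numeric(center),
                            scale = as.numeric(scl), stringsAsFactors = FALSE)
    }
    sc <- scaling[match(rec$variable_id, scaling$variable_id), ]
    val <- (val - sc$center) / sc$scale
  } else {
    scaling <- data.frame(variable_id = character(0), center = numeric(0),
                          scale = numeric(0))
  }

  key <- (i - 1) + nP * ((j - 1) + nV * (b - 1)) + 1
  sums <- numeric(nP * nV * nBins)
  cnts <- integer(nP * nV * nBins)
  if (length(key)) {
    agg <- rowsum(cbind(val, rep(1, length(val))), key)
    at <- as.integer(rownames(agg))
    sums[at] <- agg[, 1L]
    cnts[at] <- as.integer(agg[, 2L])
  }
  vals <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), 0)

  dn <- list(patients, variables, sprintf("bin%d", seq_len(nBins)))
  new("TensorizedCohort",
      values = array(vals, dim = c(nP, nV, nBins), dimnames = dn),
      counts = array(cnts, dim = c(nP, nV, nBins), dimnames = dn),
      labels = stats::setNames(cohort$label, patients)[patients],
      binWidthMonths = binWidthMonths,
      scaling = scaling,
      dropped = dropped)
}

#' Propensity-score match controls to cases
#'
#' Estimates the cohorts' covariate separability as the average held-out
#' accuracy of repeated logistic fits on balanced resamples, selects 1:1
#' nearest-neighbour controls on the logit of the propensity score (without
#' replacement, no caliper), and re-estimates separability on the matched
#' cohort, stopping the post-match averaging early once the running mean is
#' within `tolerance` of `targetAccuracy` (inseparability is 0.5). Both
#' held-out and in-sample separabilities are reported.
#'
#' @param cohort data.frame with `patient_id`, `label` and covariate columns.
#' @param covariates Covariate column names (default: all columns other than
#'   `patient_id`, `label`, `index_shift_days`).
#' @param nIterations Maximum logistic fits per separability estimate
#'   (default 100).
#' @param targetAccuracy Stopping target (default 0.5).
#' @param tolerance Early-stop tolerance around the target (default 0.02).
#' @param seed Integer seed.
#' @return A list of class `matchResult`: `matchedControlIds`,
#'   `preMatchSeparability`, `postMatchSeparability` (held-out),
#'   `preMatchInsample`, `postMatchInsample`, `iterationsRun`,
#'   `unmatchedCases`.
#' @export
propensityMatch <- function(cohort, covariates = NULL, nIterations = 100L,
                            targetAccuracy = 0.5, tolerance = 0.02,
                            seed = 1L) {
  stopifnot(sum(cohort$label == "case") >= 2L,
            sum(cohort$label == "control") >= 2L)
  if (is.null(covariates)) {
    covariates <- setdiff(names(cohort),
                          c("patient_id", "label", "index_shift_days"))
  }
  X <- stats::model.matrix(~ . - 1, data = cohort[, covariates, drop = FALSE])
  y <- as.integer(cohort$label == "case")

  separability <- function(idx, seedOff, earlyStop = FALSE) {
    accs <- numeric(0)
    for (it in seq_len(nIterations)) {
      set.seed(seed + seedOff + it)
      pos <- idx[y[idx] == 1L]
      neg <- idx[y[idx] == 0L]
      nb <- min(length(pos), length(neg))
      bal <- c(sample(pos, nb), sample(neg, nb))
      testIdx <- bal[stratifiedSplit(y[bal], 0.3, seed + seedOff + 7919L * it)]
      trainIdx <- setdiff(bal, testIdx)
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X[trainIdx, , drop = FALSE]), y[trainIdx],
                       family = stats::binomial()))
      eta <- cbind(1, X[testIdx, , drop = FALSE]) %*% fit$coefficients
      accs <- c(accs, mean((eta > 0) == (y[testIdx] == 1L)))
      if (earlyStop && it >= 10L &&
          abs(mean(accs) - targetAccuracy) <= tolerance) break
    }
    list(mean = mean(accs), iterations = length(accs))
  }
  insample <- function(idx) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X[idx, , drop = FALSE]), y[idx],
                     family = stats::binomial()))
    eta <- cbind(1, X[idx, , drop = FALSE]) %*% fit$coefficients
    mean((eta > 0) == (y[idx] == 1L))
  }

  all <- seq_len(nrow(cohort))
  pre <- separability(all, 0L)

  ## propensity model on the full cohort; match on the logit
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  eta <- drop(cbind(1, X) %*% fit$coefficients)
  if (any(!is.finite(eta)) ||
      (min(eta[y == 1L]) > max(eta[y == 0L])) ||
      (max(eta[y == 1L]) < min(eta[y == 0L]))) {
    warning("non-overlapping propensity supports; best-effort matching")
  }
  cases <- which(y == 1L)
  controls <- which(y == 0L)
  set.seed(seed)
  caseOrder <- cases[order(-eta[cases])]
  avail <- rep(TRUE, length(controls))
  pick <- integer(0)
  unmatched <- 0L
  for (ci in caseOrder) {
    if (!any(avail)) {
      unmatched <- unmatched + 1L
      next
    }
    d <- abs(eta[controls] - eta[ci])
    d[!avail] <- Inf
    k <- which.min(d)
    avail[k] <- FALSE
    pick <- c(pick, controls[k])
  }
  if (unmatched > 0L) {
    warning(sprintf("%d cases left unmatched (controls exhausted)", unmatched))
  }
  matchedIdx <- c(cases, pick)
  post <- separability(matchedIdx, 20000L, earlyStop = TRUE)

  structure(list(matchedControlIds = cohort$patient_id[pick],
                 preMatchSeparability = pre$mean,
                 postMatchSeparability = post$mean,
                 preMatchInsample = insample(all),
                 postMatchInsample = insample(matchedIdx),
                 iterationsRun = post$iterations,
                 unmatchedCases = unmatched),
            class = "matchResult")
}

#' @export
print.matchResult <- function(x, ...) {
  cat(sprintf(paste0("propensity match: separability %.3f -> %.3f (held-out),",
                     " %.3f -> %.3f (in-sample), %d matched controls, %d iterations\n"),
              x$preMatchSeparability, x$postMatchSeparability,
              x$preMatchInsample, x$postMatchInsample,
              length(x$matchedControlIds), x$iterationsRun))
  invisible(x)
}
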