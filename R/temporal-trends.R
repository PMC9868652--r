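#' Windowed per-patient means at fixed pre-diagnosis anchor months
#'
#' For each anchor month `m`, averages the measurements recorded within
#' `halfWindowMonths` months on either side of that month before the index
#' date (anchor windows are allowed to overlap, e.g. anchors 0 and 3 share
#' months 1-2). Patients with no measurement in a window simply have no row
#' for that anchor (a missing marker, not 0: these means feed regression, not
#' the network).
#'
#' @param records Pre-diagnosis records (patient_id, variable_id, t, value).
#' @param cohort Cohort table with `patient_id` and `label`.
#' @param anchors Anchor months before index (default `c(0, 3, 6, 12)`).
#' @param halfWindowMonths Window half-width in months (default 2).
#' @return data.frame (patient_id, label, variable_id, anchor, mean, n).
#' @export
windowedMeans <- function(records, cohort, anchors = c(0, 3, 6, 12),
                          halfWindowMonths = 2) {
  unknown <- setdiff(records$patient_id, cohort$patient_id)
  if (length(unknown)) {
    stop(sprintf("record with unknown patient: %s", unknown[1L]))
  }
  m <- -records$t / DAYS_PER_MONTH
  lab <- stats::setNames(as.character(cohort$label), cohort$patient_id)
  out <- data.frame()
  for (a in anchors) {
    sel <- abs(m - a) <= halfWindowMonths
    if (!any(sel)) next
    rec <- records[sel, , drop = FALSE]
    key <- paste(rec$patient_id, rec$variable_id, sep = "\r")
    agg <- rowsum(cbind(rec$value, 1), key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    out <- rbind(out, data.frame(
      patient_id = vapply(parts, `[`, "", 1L),
      variable_id = vapply(parts, `[`, "", 2L),
      anchor = a,
      mean = agg[, 1L] / agg[, 2L],
      n = as.integer(agg[, 2L]),
      row.names = NULL))
  }
  out$label <- unname(lab[out$patient_id])
  out[, c("patient_id", "label", "variable_id", "anchor", "mean", "n")]
}

#' Normal-range-adjusted slope of anchor means
#'
#' Ordinary least squares of the anchor means on time, with the time axis
#' oriented so that values increasing toward diagnosis yield a positive
#' slope (regressor `-anchor`). The raw coefficient (value/month) is divided
#' by the diagonal slope of the normal-range window,
#' `(high - low) / (max(anchors) - min(anchors))`, giving a dimensionless
#' adjusted slope: a series climbing from `low` to `high` across the full
#' anchor span scores exactly 1.
#'
#' @param anchorMeans Numeric vector of per-anchor means (NA = missing).
#' @param anchors Anchor months, same length.
#' @param low,high Normal-range bounds (`low < high`).
#' @return A list (coefficient, coefficientAdjusted, nAnchors); both
#'   coefficients `NA` (flagged via `nAnchors < 2`) when fewer than two
#'   anchors are non-missing.
#' @export
adjustedSlope <- function(anchorMeans, anchors, low, high) {
  stopifnot(length(anchorMeans) == length(anchors), low < high)
  ok <- is.finite(anchorMeans)
  if (sum(ok) < 2L) {
    return(list(coefficient = NA_real_, coefficientAdjusted = NA_real_,
                nAnchors = sum(ok)))
  }
  x <- -anchors[ok]
  yv <- anchorMeans[ok]
  slope <- stats::cov(x, yv) / stats::var(x)
  diagSlope <- (high - low) / (max(anchors) - min(anchors))
  list(coefficient = slope, coefficientAdjusted = slope / diagSlope,
       nAnchors = sum(ok))
}

#' Group-level temporal trends for a set of variables
#'
#' Computes windowed per-patient anchor means, averages them per group
#' (case/control) and anchor, and fits the adjusted slope per variable and
#' group on those group means. Per-patient regression is available with
#' `perPatient = TRUE` (slopes averaged over patients with >= 2 anchors).
#'
#' @inheritParams windowedMeans
#' @param normalRanges data.frame (variable_id, low, high).
#' @param variables Variables to analyse (default: all in `normalRanges`).
#' @param perPatient Fit per-patient slopes and average them (default FALSE:
#'   regression on group means).
#' @return A list: `means` (variable_id, label, anchor, mean, n_patients) and
#'   `trends` (variable_id, label, coefficient, coefficient_adjusted).
#' @export
temporalTrends <- function(records, cohort, normalRanges, variables = NULL,
                           anchors = c(0, 3, 6, 12), halfWindowMonths = 2,
                           perPatient = FALSE) {
  variables <- variables %||% normalRanges$variable_id
  wm <- windowedMeans(records[records$variable_id %in% variables, ,
                              drop = FALSE],
                      cohort, anchors, halfWindowMonths)
  means <- stats::aggregate(mean ~ variable_id + label + anchor, wm, mean)
  nPat <- stats::aggregate(patient_id ~ variable_id + label + anchor, wm,
                           function(z) length(unique(z)))
  means <- merge(means, nPat, by = c("variable_id", "label", "anchor"))
  names(means)[names(means) == "patient_id"] <- "n_patients"

  trends <- data.frame()
  for (v in variables) {
    nr <- normalRanges[normalRanges$variable_id == v, ]
    if (nrow(nr) == 0L) stop(sprintf("no normal range for variable %s", v))
    for (g in unique(means$label)) {
      if (perPatient) {
        sub <- wm[wm$variable_id == v & wm$label == g, ]
        sl <- vapply(split(sub, sub$patient_id), function(d) {
          full <- stats::setNames(rep(NA_real_, length(anchors)),
                                  as.character(anchors))
          full[as.character(d$anchor)] <- d$mean
          adjustedSlope(full, anchors, nr$low, nr$high)$coefficientAdjusted
        }, numeric(1L))
        sl <- sl[is.finite(sl)]
        co <- if (length(sl)) mean(sl) else NA_real_
        trends <- rbind(trends, data.frame(
          variable_id = v, label = g, coefficient = NA_real_,
          coefficient_adjusted = co))
      } else {
        sub <- means[means$variable_id == v & means$label == g, ]
        full <- stats::setNames(rep(NA_real_, length(anchors)),
                                as.character(anchors))
        full[as.character(sub$anchor)] <- sub$mean
        sl <- adjustedSlope(full, anchors, nr$low, nr$high)
        trends <- rbind(trends, data.frame(
          variable_id = v, label = g, coefficient = sl$coefficient,
          coefficient_adjusted = sl$coefficientAdjusted))
      }
    }
  }
  list(means = means, trends = trends)
}
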