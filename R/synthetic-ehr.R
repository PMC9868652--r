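#' Configuration for the synthetic longitudinal-lab cohort generator
#'
#' The generator emulates the kind of cohort these models are built for:
#' irregular hospital visits (a homogeneous Poisson process per patient), high
#' per-visit missingness, control trajectories stationary inside the normal
#' range, and case trajectories in the designated signal composites drifting
#' linearly in within-variable standard-deviation units as the index
#' (diagnosis) date approaches, so the signal is strongest near t = 0.
#' Covariates are drawn with a stated confounding link to the label (a
#' Gaussian/Bernoulli discriminant pair equivalent to a logistic link) so
#' propensity matching has measurable work to do (about 0.7 pre-match
#' separability by design).
#'
#' @param nCases,nControls Patient counts (each at least 1).
#' @param taxonomy A [Taxonomy-class]; defaults to [syntheticTaxonomy()].
#' @param lookbackMonths Months of pre-index history (default 60).
#' @param visitRate Expected visits per patient per year (default 12).
#' @param missingness Probability a variable is unmeasured at a visit (default
#'   0.7, emulating highly missing lab panels).
#' @param signalGroups Character vector of composite names (under
#'   `signalStrategy`) carrying the case/control signal.
#' @param signalStrategy Strategy naming the signal composites (default "g1").
#' @param driftPerMonth Signed effect size, in within-variable SD units, added
#'   to case trajectories per month approaching the index date (default 0).
#' @param rampMonths Months before index over which the drift acts (default
#'   24): the case shift at m months before index is
#'   `driftPerMonth * sd * max(0, rampMonths - m)`.
#' @param noiseSd Measurement noise scale in within-variable SD units
#'   (default 1).
#' @param postIndexMonths Months of post-index case records generated so the
#'   pre-diagnosis filter has records to remove (default 3).
#' @param seed Integer seed; identical config + seed reproduce the cohort
#'   exactly.
#' @return A classed list of validated generator settings.
#' @export
generatorConfig <- function(nCases, nControls, taxonomy = syntheticTaxonomy(),
                            lookbackMonths = 60, visitRate = 12,
                            missingness = 0.7, signalGroups = character(0),
                            signalStrategy = "g1", driftPerMonth = 0,
                            rampMonths = 24, noiseSd = 1, postIndexMonths = 3,
                            seed = 1L) {
  if (nCases < 1 || nControls < 1) {
    stop("configuration error: nCases and nControls must each be at least 1")
  }
  if (missingness < 0 || missingness > 1) {
    stop("configuration error: missingness must lie in [0, 1]")
  }
  if (length(signalGroups)) {
    known <- composites(taxonomy, signalStrategy)
    bad <- setdiff(signalGroups, known)
    if (length(bad)) {
      stop(sprintf("configuration error: unknown signal group '%s' (strategy '%s' has: %s)",
                   bad[1L], signalStrategy, paste(known, collapse = ", ")))
    }
  }
  structure(list(nCases = as.integer(nCases), nControls = as.integer(nControls),
                 taxonomy = taxonomy, lookbackMonths = lookbackMonths,
                 visitRate = visitRate, missingness = missingness,
                 signalGroups = signalGroups, signalStrategy = signalStrategy,
                 driftPerMonth = driftPerMonth, rampMonths = rampMonths,
                 noiseSd = noiseSd, postIndexMonths = postIndexMonths,
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Generate a seeded synthetic cohort of longitudinal lab records
#'
#' @param config A [generatorConfig()].
#' @return A list with components
#'   \describe{
#'     \item{records}{data.frame (patient_id, variable_id, t, value); `t` is
#'       days relative to the patient's index date, negative before.}
#'     \item{cohort}{data.frame (patient_id, label, index_shift_days, age,
#'       sex, comorbidity); one row per patient.}
#'     \item{normalRanges}{data.frame (variable_id, low, high).}
#'   }
#' @details Baselines sit at the midpoint of each variable's normal range and
#'   the within-variable SD is a quarter of the range width, so the range
#'   spans roughly +/- 2 SD. Case records extend `postIndexMonths` past the
#'   index so the pre-diagnosis filter is exercised; control records end at
#'   their provisional index (t = 0), which [assignControlIndexDates()] can
#'   move earlier. Covariates: age is N(60, 10) for controls and N(69, 10)
#'   for cases; `comorbidity` is Bernoulli(0.38) / Bernoulli(0.62);
#'   `sex` is balanced and carries no signal.
#' @seealso [assignControlIndexDates()], [makePrediagnosis()]
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(config$seed)
  tax <- config$taxonomy
  vars <- taxVariables(tax)
  nV <- length(vars)

  ## normal ranges: fixed given the seed; width 40% of the center
  center <- stats::runif(nV, 20, 200)
  half <- 0.2 * center
  normalRanges <- data.frame(variable_id = vars, low = center - half,
                             high = center + half, stringsAsFactors = FALSE)
  sigma <- half / 2

  ## which variables carry signal
  signalVar <- rep(FALSE, nV)
  if (length(config$signalGroups)) {
    sm <- strategyMap(tax, config$signalStrategy)
    compOfVar <- unname(sm[comboMap(tax)[vars]])
    signalVar <- compOfVar %in% config$signalGroups
  }

  n <- config$nCases + config$nControls
  ids <- c(sprintf("case_%03d", seq_len(config$nCases)),
           sprintf("ctrl_%03d", seq_len(config$nControls)))
  isCase <- rep(c(TRUE, FALSE), c(config$nCases, config$nControls))

  ## confounded covariates (label-conditional draws <=> logistic link)
  age <- stats::rnorm(n, ifelse(isCase, 69, 60), 10)
  comorbidity <- stats::rbinom(n, 1L, ifelse(isCase, 0.62, 0.38))
  sex <- stats::rbinom(n, 1L, 0.5)
  cohort <- data.frame(patient_id = ids,
                       label = factor(ifelse(isCase, "case", "control"),
                                      levels = c("control", "case")),
                       index_shift_days = 0,
                       age = age, sex = sex, comorbidity = comorbidity,
                       stringsAsFactors = FALSE)

  lookbackDays <- config$lookbackMonths * DAYS_PER_MONTH
  postDays <- ifelse(isCase, config$postIndexMonths * DAYS_PER_MONTH, 0)
  spanDays <- lookbackDays + postDays
  nVisits <- stats::rpois(n, config$visitRate * spanDays / 365.25)

  pidx <- rep.int(seq_len(n), nVisits)
  tVisit <- stats::runif(length(pidx), -lookbackDays, postDays[pidx])

  ## per visit, each variable measured with probability 1 - missingness
  nMeasPerVisit <- stats::rbinom(length(pidx), nV, 1 - config$missingness)
  ridx <- rep.int(seq_along(pidx), nMeasPerVisit)
  vidx <- unlist(lapply(nMeasPerVisit, function(k) {
    if (k == 0L) integer(0) else sample.int(nV, k)
  }), use.names = FALSE)

  pat <- pidx[ridx]
  tt <- tVisit[ridx]
  monthsBefore <- pmin(pmax(-tt / DAYS_PER_MONTH, 0), config$rampMonths)
  drift <- ifelse(isCase[pat] & signalVar[vidx],
                  config$driftPerMonth * sigma[vidx] *
                    (config$rampMonths - monthsBefore),
                  0)
  value <- center[vidx] + drift +
    config$noiseSd * sigma[vidx] * stats::rnorm(length(pat))

  records <- data.frame(patient_id = ids[pat], variable_id = vars[vidx],
                        t = tt, value = value, stringsAsFactors = FALSE)
  records <- records[order(match(records$patient_id, ids), records$t), ,
                     drop = FALSE]
  rownames(records) <- NULL
  list(records = records, cohort = cohort, normalRanges = normalRanges)
}

#' Assign random index dates to controls matching a target record reduction
#'
#' Cases lose a known per-variable fraction of their measurements when records
#' at or after diagnosis are removed. To put controls through the same
#' truncation, each control receives a random index date drawn so that
#' truncating its history reproduces, in expectation, the mean of the supplied
#' per-variable reduction fractions. With visit times uniform over the
#' lookback window `[-L, 0)`, shifting a control's index earlier by `delta`
#' days removes an expected fraction `delta / L`; `delta` is drawn uniformly
#' on `[max(0, 2f - 1) L, min(1, 2f) L]`, whose mean is `f L`. The boundary
#' cases are exact: `f = 0` removes nothing and `f = 1` places the index
#' before every measurement.
#'
#' @param records,cohort As returned by [simulateCohort()].
#' @param reductionProfile Named numeric vector of per-variable reduction
#'   fractions in `[0, 1]` (or a single unnamed fraction).
#' @param lookbackMonths Lookback window the records were generated over.
#' @param seed Integer seed; deterministic given (inputs, seed).
#' @return A list (records, cohort) with control record times re-expressed
#'   relative to the new index date and `cohort$index_shift_days` set to the
#'   number of days each control's index moved earlier.
#' @export
assignControlIndexDates <- function(records, cohort, reductionProfile,
                                    lookbackMonths = 60, seed = 1L) {
  f <- unname(reductionProfile)
  if (any(f < 0 | f > 1)) {
    stop("reduction fractions must lie in [0, 1]")
  }
  fbar <- mean(f)
  set.seed(seed)
  L <- lookbackMonths * DAYS_PER_MONTH
  ctrl <- which(cohort$label == "control")
  lo <- max(0, 2 * fbar - 1) * L
  hi <- min(1, 2 * fbar) * L
  delta <- stats::runif(length(ctrl), lo, hi)
  cohort$index_shift_days[ctrl] <- delta
  shift <- stats::setNames(rep(0, nrow(cohort)), cohort$patient_id)
  shift[cohort$patient_id[ctrl]] <- delta
  records$t <- records$t + shift[records$patient_id]
  list(records = records, cohort = cohort)
}

#' Write a simulated cohort as delimited text
#'
#' @param sim A list as returned by [simulateCohort()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly. Files: `records.csv`, `cohort.csv`,
#'   `normal_ranges.csv`.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(sim$normalRanges, file.path(dir, "normal_ranges.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#' @param dir Directory containing the three CSV files.
#' @return A list (records, cohort, normalRanges).
#' @export
readCohort <- function(dir) {
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  cohort$label <- factor(cohort$label, levels = c("control", "case"))
  list(records = utils::read.csv(file.path(dir, "records.csv"),
                                 stringsAsFactors = FALSE),
       cohort = cohort,
       normalRanges = utils::read.csv(file.path(dir, "normal_ranges.csv"),
                                      stringsAsFactors = FALSE))
}
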