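toyRecords <- function(ts, patient = "p1", variable = "v1") {
  data.frame(patient_id = patient, variable_id = variable, t = ts,
             value = seq_along(ts), stringsAsFactors = FALSE)
}
toyCohort <- function(ids = "p1", label = "case") {
  data.frame(patient_id = ids,
             label = factor(rep(label, length.out = length(ids)),
                            levels = c("control", "case")),
             stringsAsFactors = FALSE)
}

test_that("pre-diagnosis filter removes records at or after the index date", {
  rec <- toyRecords(c(-10, 0, 5))
  out <- makePrediagnosis(rec, toyCohort())
  expect_equal(out$t, -10)
  expect_equal(nrow(makePrediagnosis(rec[0, ], toyCohort())), 0L)
  ## 7 records, 3 at t >= 0 -> 4 survive, order preserved
  rec7 <- toyRecords(c(-300, -200, -100, -1, 0, 3, 60))
  out7 <- makePrediagnosis(rec7, toyCohort())
  expect_equal(out7$t, c(-300, -200, -100, -1))
  expect_error(makePrediagnosis(toyRecords(-5, patient = "ghost"), toyCohort()),
               "unknown patient: ghost")
})

test_that("censoring keeps records strictly more than k months before index", {
  co <- toyCohort()
  rec <- toyRecords(c(-5, -100, -400))
  expect_equal(censorAtMonths(rec, co, 0)$t,
               makePrediagnosis(rec, co)$t)
  ## exactly -12 months is removed under k = 12 (strict inequality)
  onEdge <- toyRecords(-12 * DAYS_PER_MONTH)
  expect_equal(nrow(censorAtMonths(onEdge, co, 12)), 0L)
  ## months -6, -13, -20 with k = 12 -> 2 survive
  fix <- toyRecords(c(-6, -13, -20) * DAYS_PER_MONTH)
  expect_equal(nrow(censorAtMonths(fix, co, 12)), 2L)
  expect_error(censorAtMonths(rec, co, -1), "nonnegative")
})

test_that("filters obey idempotence and composition laws", {
  set.seed(3)
  rec <- toyRecords(runif(400, -1000, 100))
  co <- toyCohort()
  once <- makePrediagnosis(rec, co)
  expect_identical(makePrediagnosis(once, co), once)
  k1 <- censorAtMonths(rec, co, 4)
  both <- censorAtMonths(k1, co, 9)
  expect_identical(both, censorAtMonths(rec, co, 9))
  expect_identical(censorAtMonths(censorAtMonths(rec, co, 9), co, 4),
                   censorAtMonths(rec, co, 9))
})

test_that("tensorize places, averages and zero-fills as specified", {
  co <- toyCohort()
  ## one measurement at exactly -1 month lands in bin 1 (most recent)
  one <- data.frame(patient_id = "p1", variable_id = "v1",
                    t = -1 * DAYS_PER_MONTH, value = 7)
  tc <- tensorize(one, co, "v1", nBins = 5, binWidthMonths = 1,
                  standardize = FALSE)
  expect_equal(as.numeric(gridValues(tc)["p1", "v1", ]), c(7, 0, 0, 0, 0))
  ## two measurements in one bin average
  two <- data.frame(patient_id = "p1", variable_id = "v1",
                    t = c(-10, -20), value = c(4, 6))
  tc2 <- tensorize(two, co, "v1", nBins = 3, binWidthMonths = 1,
                   standardize = FALSE)
  expect_equal(as.numeric(gridValues(tc2)["p1", "v1", ]), c(5, 0, 0))
  ## five measurements across three bins match hand-computed means:
  ## months 0.5, 0.9 -> bin 1; 1.5 -> bin 2; 2.2, 2.8 -> bin 3
  five <- data.frame(patient_id = "p1", variable_id = "v1",
                     t = -c(0.5, 0.9, 1.5, 2.2, 2.8) * DAYS_PER_MONTH,
                     value = c(1, 3, 10, 4, 8))
  tc5 <- tensorize(five, co, "v1", nBins = 4, binWidthMonths = 1,
                   standardize = FALSE)
  expect_equal(as.numeric(gridValues(tc5)["p1", "v1", ]), c(2, 10, 6, 0))
})

test_that("tensorization conserves the raw sums it retains", {
  sim <- smallSim()
  rec <- makePrediagnosis(sim$records, sim$cohort)
  tc <- suppressMessages(
    tensorize(rec, sim$cohort, taxVariables(syntheticTaxonomy()),
              nBins = 12, binWidthMonths = 2, standardize = FALSE))
  binned <- apply(gridValues(tc) * tc@counts, c(1, 2), sum)
  raw <- rowsum(rec$value, paste(rec$patient_id, rec$variable_id, sep = "|"))
  for (k in sample(nrow(raw), 25)) {
    key <- strsplit(rownames(raw)[k], "|", fixed = TRUE)[[1]]
    expect_equal(unname(binned[key[1], key[2]]), unname(raw[k, 1]),
                 tolerance = 1e-10)
  }
  ## missing bins are exactly zero
  expect_true(all(gridValues(tc)[tc@counts == 0] == 0))
  ## post-index and beyond-window records are dropped with counts
  expect_named(tc@dropped, c("post_index", "beyond_window"))
})

test_that("tensorize reports unknown patients and variables", {
  expect_error(tensorize(toyRecords(-5, patient = "ghost"), toyCohort(), "v1",
                         nBins = 2), "unknown patient")
  expect_error(tensorize(toyRecords(-5, variable = "vX"), toyCohort(), "v1",
                         nBins = 2), "not in the requested grid")
})

test_that("label-independent covariates yield chance separability", {
  set.seed(8)
  co <- data.frame(patient_id = sprintf("p%d", 1:240),
                   label = factor(rep(c("case", "control"), each = 120),
                                  levels = c("control", "case")),
                   age = rnorm(240, 60, 10), x = rnorm(240))
  pm <- propensityMatch(co, nIterations = 40, seed = 4)
  expect_lt(abs(pm$preMatchSeparability - 0.5), 0.1)
  expect_lt(abs(pm$postMatchSeparability - 0.5), 0.1)
  expect_length(pm$matchedControlIds, 120L)
})

test_that("perfectly separating covariates trigger the degenerate path", {
  co <- data.frame(patient_id = sprintf("p%d", 1:120),
                   label = factor(rep(c("case", "control"), each = 60),
                                  levels = c("control", "case")),
                   marker = rep(c(5, -5), each = 60))
  expect_warning(pm <- propensityMatch(co, nIterations = 15, seed = 2),
                 "non-overlapping")
  expect_gt(pm$preMatchSeparability, 0.95)
  ## matching cannot repair deterministic separation
  expect_gt(pm$postMatchSeparability, 0.9)
})

test_that("matching on confounded covariates moves separability toward 0.5", {
  sim <- smallSim(seed = 21, nCases = 80, nControls = 320, drift = 0)
  pm <- propensityMatch(sim$cohort[, c("patient_id", "label", "age", "sex",
                                       "comorbidity")],
                        seed = 6)
  expect_gt(pm$preMatchSeparability, 0.55)
  expect_lt(pm$postMatchSeparability, pm$preMatchSeparability + 0.02)
  expect_lt(abs(pm$postMatchSeparability - 0.5),
            abs(pm$preMatchSeparability - 0.5))
  expect_length(pm$matchedControlIds, 80L)
  expect_lte(pm$iterationsRun, 100L)
})
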