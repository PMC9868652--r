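test_that("configuration violations are rejected with named errors", {
  expect_error(generatorConfig(nCases = 0, nControls = 10), "at least 1")
  expect_error(generatorConfig(10, 10, missingness = 1.2), "missingness")
  expect_error(generatorConfig(10, 10, signalGroups = "no such group"),
               "unknown signal group 'no such group'")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- generatorConfig(15, 15, taxonomy = syntheticTaxonomy(),
                         lookbackMonths = 12, seed = 99)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$normalRanges, b$normalRanges)
})

test_that("realized missingness tracks the configured probability", {
  cfg <- generatorConfig(60, 60, taxonomy = syntheticTaxonomy(),
                         lookbackMonths = 24, missingness = 0.5, seed = 5)
  sim <- simulateCohort(cfg)
  nV <- length(taxVariables(syntheticTaxonomy()))
  ## with 20 variables at 50% missingness, visits with zero measurements are
  ## vanishingly rare, so distinct (patient, t) pairs count the visits
  visits <- nrow(unique(sim$records[, c("patient_id", "t")]))
  expect_gt(visits, 1000)
  realized <- 1 - nrow(sim$records) / (visits * nV)
  expect_lt(abs(realized - 0.5), 0.02)
})

test_that("zero drift leaves case and control distributions exchangeable", {
  pvals <- vapply(1:12, function(s) {
    sim <- smallSim(seed = 100 + s, nCases = 25, nControls = 25, drift = 0)
    v <- sim$records[sim$records$variable_id == "liver_c1_v1", ]
    grp <- sim$cohort$label[match(v$patient_id, sim$cohort$patient_id)]
    stats::t.test(v$value[grp == "case"], v$value[grp == "control"])$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_gt(max(pvals), 0.2)
})

test_that("injected drift touches only the signal composite's variables", {
  tax <- syntheticTaxonomy()
  base <- generatorConfig(20, 20, taxonomy = tax, lookbackMonths = 24,
                          driftPerMonth = 0, seed = 77)
  drifted <- generatorConfig(20, 20, taxonomy = tax, lookbackMonths = 24,
                             signalGroups = "liver function group",
                             driftPerMonth = 0.2, seed = 77)
  a <- simulateCohort(base)
  b <- simulateCohort(drifted)
  expect_identical(a$records[, c("patient_id", "variable_id", "t")],
                   b$records[, c("patient_id", "variable_id", "t")])
  sm <- strategyMap(tax, "g1")
  liverVars <- names(comboMap(tax))[
    sm[comboMap(tax)] == "liver function group"]
  isCase <- grepl("^case", a$records$patient_id)
  inSignal <- a$records$variable_id %in% liverVars
  expect_identical(a$records$value[!(isCase & inSignal)],
                   b$records$value[!(isCase & inSignal)])
  expect_true(all(a$records$value[isCase & inSignal] !=
                    b$records$value[isCase & inSignal]))
  ## drift is positive and strongest near the index date
  delta <- b$records$value - a$records$value
  near <- isCase & inSignal & a$records$t > -6 * DAYS_PER_MONTH
  far <- isCase & inSignal & a$records$t < -18 * DAYS_PER_MONTH
  expect_gt(mean(delta[near]), mean(delta[far]))
})

test_that("case signal strengthens toward the index date in the records", {
  sim <- smallSim()
  tax <- syntheticTaxonomy()
  v <- sim$records[sim$records$variable_id == "liver_c1_v1", ]
  lab <- sim$cohort$label[match(v$patient_id, sim$cohort$patient_id)]
  m <- -v$t / DAYS_PER_MONTH
  caseNear <- v$value[lab == "case" & m <= 6 & m > 0]
  caseFar <- v$value[lab == "case" & m > 18]
  ctrl <- v$value[lab == "control"]
  expect_gt(mean(caseNear), mean(ctrl))
  expect_gt(mean(caseNear), mean(caseFar))
})

test_that("control index assignment reproduces the target reduction", {
  sim <- smallSim(seed = 31, nCases = 10, nControls = 400, drift = 0)
  ## boundary: zero reduction leaves every control index after all records
  z <- assignControlIndexDates(sim$records, sim$cohort, 0,
                               lookbackMonths = 24, seed = 1)
  expect_identical(z$records$t, sim$records$t)
  ## boundary: full reduction puts the index before every measurement
  o <- assignControlIndexDates(sim$records, sim$cohort, 1,
                               lookbackMonths = 24, seed = 1)
  ctrlRec <- grepl("^ctrl", o$records$patient_id)
  expect_true(all(o$records$t[ctrlRec] >= 0))
  ## f = 0.3: mean realized per-control reduction within +/- 0.05
  p <- assignControlIndexDates(sim$records, sim$cohort,
                               setNames(rep(0.3, 20),
                                        taxVariables(syntheticTaxonomy())),
                               lookbackMonths = 24, seed = 2)
  removedByPatient <- tapply(p$records$t >= 0, p$records$patient_id, mean)
  ctrl <- grepl("^ctrl", names(removedByPatient))
  expect_lt(abs(mean(removedByPatient[ctrl]) - 0.3), 0.05)
  expect_error(assignControlIndexDates(sim$records, sim$cohort, 1.5),
               "\\[0, 1\\]")
})

test_that("cohort tables round-trip through the CSV writer", {
  sim <- smallSim(seed = 12, nCases = 5, nControls = 5)
  dir <- withr::local_tempdir()
  writeCohort(sim, dir)
  back <- readCohort(dir)
  expect_equal(back$records$value, sim$records$value)
  expect_equal(back$cohort$label, sim$cohort$label)
  expect_equal(back$normalRanges, sim$normalRanges)
})
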