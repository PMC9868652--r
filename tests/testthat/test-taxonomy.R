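test_that("packaged lab taxonomy has the full three-level structure", {
  tax <- validateTaxonomy(labTaxonomy())
  expect_equal(unname(attr(tax, "counts")), c(206L, 32L))
  expect_setequal(strategyNames(tax), c("g1", "g2", "g3"))
  expect_setequal(composites(tax, "g1"),
                  c("white blood cell group", "red blood cell group",
                    "liver function group", "kidney group", "diabetes group"))
  expect_length(composites(tax, "g2"), 3L)
  expect_length(composites(tax, "g3"), 7L)
  ## residual composites exist under the correlation strategies
  expect_true("comp3" %in% composites(tax, "g2"))
  expect_true("comp7" %in% composites(tax, "g3"))
  ## the higher-threshold strategy must nest inside the lower-threshold one:
  ## every non-residual g3 component lies within a single g2 composite
  g2 <- strategyMap(tax, "g2")
  g3 <- strategyMap(tax, "g3")
  for (cp in setdiff(composites(tax, "g3"), "comp7")) {
    members <- names(g3)[g3 == cp]
    expect_length(unique(unname(g2[members])), 1L)
  }
})

test_that("partition violations raise named diagnostics", {
  expect_error(Taxonomy(c(a = "c1", a = "c2"),
                        list(g = c(c1 = "x", c2 = "x"))),
               "two combos")
  expect_error(Taxonomy(c(a = "c1", b = "c2"),
                        list(g = c(c1 = "x"))),
               "combo missing from the strategy: c2")
  expect_error(Taxonomy(c(a = "c1"), list(g = c(c1 = "x", zz = "y"))),
               "unknown combo: zz")
  expect_error(strategyMap(tinyTaxonomy(), "nope"), "unknown grouping strategy")
})

test_that("taxonomy YAML round-trips losslessly", {
  tax <- tinyTaxonomy()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeTaxonomy(tax, path)
  back <- readTaxonomy(path)
  expect_equal(comboMap(back), comboMap(tax))
  expect_equal(strategyMap(back, "g"), strategyMap(tax, "g"))
})

## construct five combo embeddings with controlled correlation structure:
## |r(1,2)| ~ 0.5, |r(2,3)| ~ 0.35, all other pairs near 0
correlatedFixture <- function(seed = 42L, n = 4000L) {
  set.seed(seed)
  z2 <- rnorm(n)
  E <- cbind(c1 = 0.58 * z2 + sqrt(1 - 0.58^2) * rnorm(n),
             c2 = z2,
             c3 = 0.35 * z2 + sqrt(1 - 0.35^2) * rnorm(n),
             c4 = rnorm(n), c5 = rnorm(n))
  E
}

test_that("correlation grouping matches the connected-component reading", {
  E <- correlatedFixture()
  r <- abs(cor(E))
  ## guard the fixture before asserting behaviour on it
  expect_gt(r["c1", "c2"], 0.4)
  expect_true(r["c2", "c3"] > 0.3 && r["c2", "c3"] < 0.4)
  expect_lt(r["c1", "c3"], 0.3)
  expect_lt(max(r[c("c4", "c5"), c("c1", "c2", "c3")]), 0.3)
  expect_lt(r["c4", "c5"], 0.3)

  g03 <- correlationGrouping(E, 0.3)
  expect_equal(unname(g03[c("c1", "c2", "c3")]), rep("comp1", 3L))
  expect_equal(unname(g03[c("c4", "c5")]), rep("residual", 2L))
  g04 <- correlationGrouping(E, 0.4)
  expect_equal(unname(g04[c("c1", "c2")]), rep("comp1", 2L))
  expect_equal(unname(g04[c("c3", "c4", "c5")]), rep("residual", 3L))
})

test_that("all-below-threshold and near-1 thresholds give residual-only", {
  set.seed(7)
  E <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("c", 1:6)))
  g <- correlationGrouping(E, 0.9)
  expect_equal(unname(unique(g)), "residual")
  g2 <- correlationGrouping(E, 0.999)
  expect_equal(unname(unique(g2)), "residual")
})

test_that("constant combo columns are treated as uncorrelated, with warning", {
  set.seed(1)
  E <- cbind(c1 = rnorm(50), c2 = rep(2, 50), c3 = rnorm(50))
  expect_warning(g <- correlationGrouping(E, 0.3), "constant")
  expect_equal(unname(g["c2"]), "residual")
})

test_that("grouping agrees with a union-find oracle on random matrices", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 60L
    E <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("c", 1:10)))
    ## plant a few correlated pairs
    E[, 2] <- E[, 1] * 0.7 + rnorm(n, sd = 0.7)
    E[, 5] <- E[, 4] * 0.6 + rnorm(n, sd = 0.8)
    for (th in c(0.3, 0.4)) {
      got <- correlationGrouping(E, th)
      adj <- abs(cor(E)) > th
      diag(adj) <- FALSE
      oracle <- unionFindGroups(adj)
      ## same partition up to names: two combos share a composite iff the
      ## oracle puts them in one component of size >= 2
      for (i in 1:9) for (j in (i + 1):10) {
        together <- got[i] == got[j] && got[i] != "residual"
        oracleTogether <- oracle[i] == oracle[j] && sum(oracle == oracle[i]) >= 2
        expect_identical(together, oracleTogether)
      }
      ## residual = isolated nodes
      iso <- vapply(1:10, function(i) sum(oracle == oracle[i]) == 1L, TRUE)
      expect_identical(unname(got == "residual"), iso)
    }
    ## edge monotonicity: edges at 0.4 are a subset of edges at 0.3
    expect_true(all(!(abs(cor(E)) > 0.4) | (abs(cor(E)) > 0.3)))
  }
})

test_that("every grouping output is a total partition of the combos", {
  for (seed in 1:5) {
    set.seed(seed)
    E <- matrix(rnorm(400), 40, 10, dimnames = list(NULL, paste0("c", 1:10)))
    g <- correlationGrouping(E, 0.3)
    expect_setequal(names(g), paste0("c", 1:10))
    expect_true(all(nchar(g) > 0))
    tax <- addStrategy(Taxonomy(setNames(paste0("c", 1:10), paste0("v", 1:10)),
                                list()), "gx", g)
    expect_s4_class(validateTaxonomy(tax), "Taxonomy")
  }
})
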