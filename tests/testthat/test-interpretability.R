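## independent oracle: Shapley values by explicit enumeration of all feature
## orderings (the permutation definition), exact for small p
permutationOracle <- function(f, x, background) {
  p <- ncol(x)
  perms <- as.matrix(expand.grid(rep(list(seq_len(p)), p)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == p), ,
                 drop = FALSE]
  vOf <- function(xi, cols) {
    M <- background
    if (length(cols)) M[, cols] <- matrix(xi[cols], nrow(background),
                                          length(cols), byrow = TRUE)
    mean(f(M))
  }
  phi <- matrix(0, nrow(x), p)
  for (r in seq_len(nrow(x))) {
    for (k in seq_len(nrow(perms))) {
      prev <- vOf(x[r, ], integer(0))
      for (j in seq_len(p)) {
        cols <- perms[k, 1:j]
        cur <- vOf(x[r, ], cols)
        phi[r, perms[k, j]] <- phi[r, perms[k, j]] + (cur - prev) / nrow(perms)
        prev <- cur
      }
    }
  }
  phi
}

test_that("exact Shapley values match the permutation-enumeration oracle", {
  set.seed(6)
  f <- function(M) M[, 1] * 2 - M[, 2] * M[, 3] + sin(M[, 3])
  x <- matrix(rnorm(9), 3, 3)
  bg <- matrix(rnorm(15), 5, 3)
  sv <- shapleyValues(f, x, bg, exactLimit = 12)
  expect_equal(sv$method, "exact")
  expect_equal(sv$phi, permutationOracle(f, x, bg),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("both Shapley estimators satisfy additivity exactly", {
  set.seed(7)
  f <- function(M) tanh(M %*% seq_len(ncol(M)) / ncol(M))[, 1]
  for (p in c(4L, 15L)) { # 15 exceeds exactLimit and triggers sampling
    x <- matrix(rnorm(6 * p), 6, p)
    bg <- matrix(rnorm(10 * p), 10, p)
    sv <- shapleyValues(f, x, bg, exactLimit = 12, nPermutations = 8,
                        seed = 3)
    expect_equal(sv$method, if (p == 4L) "exact" else "permutation")
    expect_equal(rowSums(sv$phi) + sv$base, sv$fx, tolerance = 1e-12)
  }
})

test_that("linear-model Shapley values recover the known closed form", {
  ## for f(x) = w'x the attribution is w_i (x_i - mean(background_i))
  set.seed(8)
  w <- c(1.5, -2, 0.5)
  f <- function(M) drop(M %*% w)
  x <- matrix(rnorm(12), 4, 3)
  bg <- matrix(rnorm(30), 10, 3)
  sv <- shapleyValues(f, x, bg)
  expected <- sweep(x, 2, colMeans(bg)) %*% diag(w)
  expect_equal(sv$phi, expected, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a perfectly predictive composite dominates every method", {
  set.seed(9)
  n <- 120
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  E <- cbind(winner = ifelse(y == "case", 1, -1) + rnorm(n, sd = 0.05),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  imp <- compositeImportance(E, y, nRepeats = 4, seed = 2)
  for (m in unique(imp$method)) {
    sub <- imp[imp$method == m, ]
    expect_equal(sub$composite[which.max(sub$importance)], "winner")
    expect_gt(max(sub$importance), 0.6)
    expect_equal(sum(sub$importance), 1, tolerance = 1e-9)
  }
})

test_that("constant embedding columns get zero importance with a warning", {
  set.seed(10)
  y <- factor(rep(c("control", "case"), 30), levels = c("control", "case"))
  E <- cbind(a = rnorm(60), flat = rep(1, 60))
  expect_warning(imp <- compositeImportance(E, y, nRepeats = 2, seed = 1),
                 "constant")
  expect_true(all(imp$importance[imp$composite == "flat"] == 0))
})

test_that("layer SHAP links units to parents and respects dead units", {
  fx <- smallCompositeFit()
  model <- fx$fit$model
  ## zero the head weights leaving composite 2 dead
  model@params$head$W[2, ] <- 0
  rep <- layerShap(model, fx$tc, backgroundSize = 15, seed = 4,
                   nPermutations = 6)
  s3 <- rep$summary[rep$summary$layer == 3, ]
  expect_equal(s3$mean_abs_shap[2], 0, tolerance = 1e-12)
  ## additivity at every explained layer
  for (d in rep$detail) {
    expect_equal(rowSums(d$phi) + d$base, d$fx, tolerance = 1e-10)
  }
  ## affiliations follow the taxonomy
  tax <- syntheticTaxonomy()
  s1 <- rep$summary[rep$summary$layer == 1, ]
  expect_equal(s1$parent, unname(comboMap(tax)[s1$unit]))
  s2 <- rep$summary[rep$summary$layer == 2, ]
  expect_equal(s2$parent, unname(strategyMap(tax, "g1")[s2$unit]))
  ## oversized background is capped with a warning
  expect_warning(layerShap(model, fx$tc, backgroundSize = 10000, seed = 1,
                           nPermutations = 2), "capped")
})

test_that("accumulated SHAP sums member variables and conserves totals", {
  tax <- Taxonomy(c(v1 = "c1", v2 = "c1", v3 = "c2", v4 = "c2"),
                  list(g = c(c1 = "A", c2 = "B")))
  vals <- c(v1 = 1, v2 = 2, v3 = 3, v4 = 4)
  acc <- accumulatedShap(vals, tax, "g")
  expect_equal(acc, c(A = 3, B = 7))
  expect_equal(accumulatedShap(vals * 0, tax, "g"), c(A = 0, B = 0))
  set.seed(3)
  r <- setNames(runif(4), names(vals))
  expect_equal(sum(accumulatedShap(r, tax, "g")), sum(r), tolerance = 1e-12)
  expect_error(accumulatedShap(c(zz = 1), tax, "g"), "missing from the strategy")
})
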