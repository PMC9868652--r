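#' Gaussian-mixture clustering initialised with K-means
#'
#' K-means centroids (seeded) initialise a full-covariance Gaussian mixture,
#' which is refined by expectation-maximisation to convergence; patients are
#' then hard-assigned by maximum responsibility. A degenerate component
#' (emptied during EM) triggers a re-seeded retry; repeated failure is an
#' error.
#'
#' @param embeddings Numeric matrix, patients x dimensions (the model's final
#'   one-dimensional embeddings; vectors are treated as one column).
#' @param nComponents Number of mixture components (default 2: the
#'   case/control subgrouping).
#' @param seed Integer seed; identical inputs + seed give identical
#'   assignments.
#' @param maxIter EM iteration cap (default 200).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param nRetries Re-seeded retries on degeneracy (default 3).
#' @return A list of class `gmmFit`: `assignments` (integer per patient),
#'   `responsibilities`, `means`, `covariances`, `weights`, `logLik`,
#'   `iterations`.
#' @export
clusterEmbeddings <- function(embeddings, nComponents = 2L, seed = 1L,
                              maxIter = 200L, tol = 1e-8, nRetries = 3L) {
  E <- as.matrix(embeddings)
  n <- nrow(E); d <- ncol(E)
  stopifnot(nComponents >= 1L, n >= nComponents)
  if (nComponents == 1L) {
    return(structure(list(assignments = rep(1L, n),
                          responsibilities = matrix(1, n, 1),
                          means = matrix(colMeans(E), 1),
                          covariances = list(stats::cov(E) + diag(1e-6, d)),
                          weights = 1, logLik = NA_real_, iterations = 0L),
                     class = "gmmFit"))
  }
  for (attempt in seq_len(nRetries)) {
    set.seed(seed + attempt - 1L)
    km <- suppressWarnings(stats::kmeans(E, centers = nComponents,
                                         nstart = 10L, iter.max = 50L))
    fit <- tryCatch(gmmEM(E, km, maxIter, tol),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      fit$assignments <- max.col(fit$responsibilities, ties.method = "first")
      class(fit) <- "gmmFit"
      return(fit)
    }
    message(sprintf("clusterEmbeddings: degenerate component, retry %d", attempt))
  }
  stop("GMM clustering failed repeatedly with degenerate components")
}

## EM for a full-covariance Gaussian mixture from a kmeans initialisation
gmmEM <- function(E, km, maxIter, tol) {
  n <- nrow(E); d <- ncol(E); K <- nrow(km$centers)
  ridge <- diag(1e-6, d)
  mu <- km$centers
  covs <- lapply(seq_len(K), function(k) {
    pts <- E[km$cluster == k, , drop = FALSE]
    if (nrow(pts) > 1L) stats::cov(pts) + ridge else diag(1, d)
  })
  w <- tabulate(km$cluster, K) / n
  logdens <- function() {
    ld <- matrix(0, n, K)
    for (k in seq_len(K)) {
      ch <- chol(covs[[k]])
      xc <- sweep(E, 2L, mu[k, ])
      q <- rowSums((xc %*% chol2inv(ch)) * xc)
      ld[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + q) + log(w[k])
    }
    ld
  }
  ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ld <- logdens()
    norm <- rowLogSumExp(ld)
    resp <- exp(ld - norm)
    llNew <- sum(norm)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("degenerate component")
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(resp[, k] * E) / nk[k]
      xc <- sweep(E, 2L, mu[k, ])
      covs[[k]] <- crossprod(xc * sqrt(resp[, k]), xc * sqrt(resp[, k])) / nk[k] + ridge
    }
    w <- nk / n
    if (iter >= maxIter || abs(llNew - ll) < tol * (abs(ll) + 1)) {
      return(list(responsibilities = resp, means = mu, covariances = covs,
                  weights = w, logLik = llNew, iterations = iter))
    }
    ll <- llNew
  }
}

#' Cluster-by-class contingency counts
#'
#' @param assignments Cluster assignment per datapoint.
#' @param labels Class label per datapoint.
#' @return A [ClusterContingency-class] with counts `n_ij` (cluster i,
#'   class j).
#' @export
clusterContingency <- function(assignments, labels) {
  if (length(assignments) == 0L) stop("empty contingency")
  tab <- table(cluster = assignments, class = labels)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  new("ClusterContingency", counts = counts)
}

#' Total entropy of a clustering against class labels
#'
#' The size-weighted sum of per-cluster class entropies,
#' \deqn{-\sum_i \sum_j (n_{ij}/n_i)\,\log(n_{ij}/n_i)\, w_{ij},}
#' with the convention `0 log 0 = 0` and natural logarithm. The per-term
#' weight defaults to the cluster weight `w_ij = n_i / N`, the standard
#' size-weighted cluster entropy, making 0 the score of a perfectly pure
#' clustering and `log(#classes)` the upper bound; the sign is flipped from
#' the raw summation (which is nonpositive as written) so lower = purer on a
#' nonnegative scale. `weights = "uniform"` uses `w_ij = 1` instead.
#'
#' @param contingency A [ClusterContingency-class] (or something accepted by
#'   [clusterContingency()] together with `labels`).
#' @param weights `"size"` (default) or `"uniform"`.
#' @param labels If `contingency` is an assignment vector, the class labels.
#' @return Nonnegative numeric; 0 iff every cluster is class-pure.
#' @export
totalEntropy <- function(contingency, weights = c("size", "uniform"),
                         labels = NULL) {
  weights <- match.arg(weights)
  if (!methods::is(contingency, "ClusterContingency")) {
    contingency <- clusterContingency(contingency, labels)
  }
  methods::validObject(contingency)
  nij <- contingency@counts
  ni <- rowSums(nij)
  N <- sum(ni)
  pij <- nij / ni
  terms <- ifelse(pij > 0, pij * log(pij), 0)
  wij <- switch(weights,
                size = matrix(ni / N, nrow(nij), ncol(nij)),
                uniform = matrix(1, nrow(nij), ncol(nij)))
  -sum(terms * wij)
}

#' Exact t-SNE projection to two dimensions (plotting aid)
#'
#' A compact exact (non-Barnes-Hut) t-distributed stochastic neighbour
#' embedding with perplexity-calibrated Gaussian affinities, early
#' exaggeration and momentum gradient descent. Intended for small cohorts and
#' figures only; the entropy score never uses it.
#'
#' @param embeddings Numeric matrix, patients x dimensions (>= 5 rows).
#' @param seed Integer seed (deterministic layout under a fixed seed).
#' @param perplexity Target perplexity (default `min(30, (n - 1) / 3)`).
#' @param maxIter Gradient iterations (default 500).
#' @return Numeric matrix, patients x 2.
#' @export
tsneProjection <- function(embeddings, seed = 1L, perplexity = NULL,
                           maxIter = 500L) {
  E <- as.matrix(embeddings)
  n <- nrow(E)
  stopifnot(n >= 5L)
  perplexity <- perplexity %||% min(30, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(E))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-Di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) } else {
        H <- log(sp) + beta * sum(Di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  exag <- 4
  for (iter in seq_len(maxIter)) {
    Pe <- if (iter <= 100) P * exag else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 250) 0.5 else 0.8
    G <- mom * G - 200 * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
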