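#' Construct a Taxonomy
#'
#' @param comboMap Named character vector mapping each level-1 variable to its
#'   combo; names are the variable ids and define the variable order.
#' @param strategies Named list of named character vectors, each mapping every
#'   combo to a composite index.
#' @return A validated [Taxonomy-class].
#' @examples
#' tax <- Taxonomy(c(alt_a = "alt", alt_b = "alt", glu_a = "glucose"),
#'                 list(g1 = c(alt = "liver function group",
#'                             glucose = "diabetes group")))
#' composites(tax, "g1")
#' @export
Taxonomy <- function(comboMap, strategies = list()) {
  obj <- new("Taxonomy", variables = names(comboMap),
             comboMap = comboMap, strategies = strategies)
  methods::validObject(obj)
  obj
}

#' Validate a taxonomy, raising a named diagnostic on any partition violation
#'
#' Checks that the combo map is a total partition of the variables and every
#' strategy a total partition of the combos. Returns the taxonomy unchanged on
#' success, with the level cardinalities attached as attribute `"counts"`.
#'
#' @param taxonomy A [Taxonomy-class].
#' @return The taxonomy, invisibly unchanged, with a `counts` attribute
#'   `c(variables = ..., combos = ...)`.
#' @export
validateTaxonomy <- function(taxonomy) {
  methods::validObject(taxonomy)
  attr(taxonomy, "counts") <- c(variables = length(taxVariables(taxonomy)),
                                combos = length(taxCombos(taxonomy)))
  taxonomy
}

#' Add or replace a grouping strategy
#'
#' @param taxonomy A [Taxonomy-class].
#' @param name Strategy name.
#' @param map Named character vector combo -> composite (total over combos).
#' @return The taxonomy with the strategy installed.
#' @export
addStrategy <- function(taxonomy, name, map) {
  taxonomy@strategies[[name]] <- map
  methods::validObject(taxonomy)
  taxonomy
}

#' Group combos by thresholded correlation of their embeddings
#'
#' Computes pairwise Pearson correlations of the one-dimensional combo
#' embeddings across patients, places an edge between two combos when
#' `|r| > threshold`, and bundles each connected component of two or more
#' combos into a composite. Combos correlated with no other combo are pooled
#' into a single residual composite.
#'
#' @param comboEmbeddings Numeric matrix, patients x combos, with combo ids as
#'   column names.
#' @param threshold Correlation cutoff in (0, 1); an edge requires strict
#'   exceedance.
#' @param residualName Composite id for the pooled uncorrelated combos.
#' @param absolute Use `|r|` (default) rather than signed r for the cutoff.
#' @return Named character vector combo -> composite (a total partition),
#'   suitable for [addStrategy()]. Connected components are named `comp1`,
#'   `comp2`, ... in order of their first combo.
#' @export
correlationGrouping <- function(comboEmbeddings, threshold,
                                residualName = "residual", absolute = TRUE) {
  stopifnot(is.matrix(comboEmbeddings), ncol(comboEmbeddings) >= 2L,
            nrow(comboEmbeddings) >= 3L)
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie strictly between 0 and 1")
  }
  combos <- colnames(comboEmbeddings)
  if (is.null(combos)) stop("comboEmbeddings must carry combo ids as colnames")
  sds <- apply(comboEmbeddings, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("constant combo column(s) treated as uncorrelated: %s",
                    paste(combos[sds == 0], collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(comboEmbeddings))
  r[!is.finite(r)] <- 0
  if (absolute) r <- abs(r)
  diag(r) <- 0
  adj <- r > threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- stats::setNames(rep(residualName, length(combos)), combos)
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes >= 2L])
  k <- 0L
  for (cid in unique(comp)) { # order of first appearance
    if (cid %in% big) {
      k <- k + 1L
      out[comp == cid] <- sprintf("comp%d", k)
    }
  }
  out
}

#' Read / write a taxonomy as YAML
#'
#' The on-disk format lists each combo's member variables and each strategy's
#' composite membership:
#' ```yaml
#' combos:
#'   alt: [alt_a, alt_b]
#' strategies:
#'   g1:
#'     liver function group: [alt]
#' ```
#'
#' @param path File path.
#' @return `readTaxonomy` returns a validated [Taxonomy-class];
#'   `writeTaxonomy` returns `path` invisibly.
#' @export
readTaxonomy <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$combos)) stop("taxonomy file lacks a 'combos' block")
  comboMap <- character(0)
  for (cb in names(doc$combos)) {
    vars <- unlist(doc$combos[[cb]])
    comboMap[vars] <- cb
  }
  strategies <- lapply(doc$strategies %||% list(), function(s) {
    sm <- character(0)
    for (cp in names(s)) sm[unlist(s[[cp]])] <- cp
    sm
  })
  Taxonomy(comboMap, strategies)
}

#' @rdname readTaxonomy
#' @param taxonomy A [Taxonomy-class] to serialize.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  cm <- comboMap(taxonomy)
  combos <- lapply(taxCombos(taxonomy), function(cb) names(cm)[cm == cb])
  names(combos) <- taxCombos(taxonomy)
  strategies <- lapply(taxonomy@strategies, function(sm) {
    cps <- unique(unname(sm))
    out <- lapply(cps, function(cp) names(sm)[sm == cp])
    names(out) <- cps
    out
  })
  yaml::write_yaml(list(combos = combos, strategies = strategies), path)
  invisible(path)
}

#' The packaged 206-variable laboratory taxonomy
#'
#' A full-cardinality example hierarchy: 206 level-1 variables in 32 combo
#' bundles of common laboratory analytes, with three grouping strategies —
#' `g1`: five expert organ-system composites (white blood cell, red blood
#' cell, liver function, kidney, diabetes groups); `g2`: three composites from
#' a correlation graph at threshold 0.3 (two correlated components plus the
#' `comp3` residual); `g3`: seven composites at threshold 0.4 (six components
#' plus the `comp7` residual). The combo and composite structure follows the
#' published organ-system/correlation groupings of this model family; the 206
#' variable-level identifiers are synthetic placeholders (`<combo>_1`,
#' `<combo>_2`, ...) distributed over the combos, since real institution lab
#' codes are not redistributable.
#'
#' @return A validated [Taxonomy-class] with 206 variables, 32 combos and
#'   strategies `g1` (5), `g2` (3) and `g3` (7 composites).
#' @export
labTaxonomy <- function() {
  readTaxonomy(system.file("extdata", "lab_taxonomy_synthetic206.yaml",
                           package = "strudem", mustWork = TRUE))
}

#' A small synthetic organ-system taxonomy for simulation studies
#'
#' Builds a compact hierarchy shaped like the full laboratory taxonomy: five
#' organ-system composites, each containing `combosPerComposite` combos of
#' `variablesPerCombo` variables. Used as the default taxonomy of the
#' synthetic cohort generator so that desk-scale experiments train in seconds.
#'
#' @param combosPerComposite Combos in each composite (default 2).
#' @param variablesPerCombo Variables in each combo (default 2).
#' @return A validated [Taxonomy-class] with strategy `g1` containing the
#'   composites `white blood cell group`, `red blood cell group`,
#'   `liver function group`, `kidney group`, `diabetes group`.
#' @export
syntheticTaxonomy <- function(combosPerComposite = 2L, variablesPerCombo = 2L) {
  groups <- list(
    "white blood cell group" = "wbc",
    "red blood cell group" = "rbc",
    "liver function group" = "liver",
    "kidney group" = "kidney",
    "diabetes group" = "gluc"
  )
  comboMap <- character(0)
  g1 <- character(0)
  for (gi in seq_along(groups)) {
    stem <- groups[[gi]]
    for (ci in seq_len(combosPerComposite)) {
      cb <- sprintf("%s_c%d", stem, ci)
      vars <- sprintf("%s_v%d", cb, seq_len(variablesPerCombo))
      comboMap[vars] <- cb
      g1[cb] <- names(groups)[gi]
    }
  }
  Taxonomy(comboMap, list(g1 = g1))
}
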