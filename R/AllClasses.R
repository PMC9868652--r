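#' Taxonomy: the three-level variable hierarchy
#'
#' A `Taxonomy` holds the ordered level-1 variables, their partition into
#' redundancy bundles ("combos", level 2), and one or more named grouping
#' strategies partitioning the combos into composite indices (level 3),
#' e.g. expert organ systems or correlation-graph components.
#'
#' @slot variables Ordered character vector of level-1 variable identifiers.
#' @slot comboMap Named character vector mapping every variable to its combo.
#' @slot strategies Named list; each element is a named character vector
#'   mapping every combo to a composite index identifier.
#'
#' @seealso [Taxonomy()], [validateTaxonomy()], [correlationGrouping()]
#' @export
setClass("Taxonomy", representation(
  variables = "character",
  comboMap = "character",
  strategies = "list"
))

setValidity("Taxonomy", function(object) {
  v <- object@variables
  cm <- object@comboMap
  if (length(v) == 0L) return("taxonomy has no variables")
  if (anyDuplicated(v)) {
    return(sprintf("variable assigned to two combos (duplicated id): %s",
                   v[duplicated(v)][1L]))
  }
  if (!setequal(names(cm), v) || length(cm) != length(v)) {
    miss <- setdiff(v, names(cm))
    if (length(miss)) return(sprintf("variable missing a combo: %s", miss[1L]))
    return("comboMap is not a total map over the variables")
  }
  combos <- unique(unname(cm[v]))
  for (s in names(object@strategies)) {
    sm <- object@strategies[[s]]
    if (!is.character(sm)) return(sprintf("strategy '%s' is not a character map", s))
    miss <- setdiff(combos, names(sm))
    if (length(miss)) {
      return(sprintf("strategy '%s': combo missing from the strategy: %s", s, miss[1L]))
    }
    extra <- setdiff(names(sm), combos)
    if (length(extra)) {
      return(sprintf("strategy '%s': unknown combo: %s", s, extra[1L]))
    }
    if (anyDuplicated(names(sm))) {
      return(sprintf("strategy '%s': combo assigned to two composites: %s",
                     s, names(sm)[duplicated(names(sm))][1L]))
    }
  }
  TRUE
})

#' TensorizedCohort: fixed-length binned value grids per patient and variable
#'
#' Longitudinal records are summarised into a patient x variable x time-bin
#' grid of within-bin means (missing bins are exactly 0, the zero-imputation
#' convention), the fixed-length encoding consumed by the structured models.
#' Bin 1 is the most recent pre-index month window.
#'
#' @slot values Numeric 3-D array, patients x variables x bins; standardized
#'   per variable when `scaling` is non-empty, with empty bins exactly 0.
#' @slot counts Integer 3-D array of the measurement counts behind each bin.
#' @slot labels Factor (`control`, `case`) aligned with the patient axis.
#' @slot binWidthMonths Width of each bin in months.
#' @slot scaling data.frame (variable_id, center, scale) used to standardize;
#'   zero rows mean raw values were binned.
#' @slot dropped Named integer vector: records dropped as post-index
#'   (`post_index`) or beyond the lookback window (`beyond_window`).
#' @export
setClass("TensorizedCohort", representation(
  values = "array",
  counts = "array",
  labels = "factor",
  binWidthMonths = "numeric",
  scaling = "data.frame",
  dropped = "integer"
))

setValidity("TensorizedCohort", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-D array")
  if (!identical(dim(object@counts), d)) return("counts and values dimensions differ")
  if (length(object@labels) != d[1L]) return("labels length != number of patients")
  if (any(object@values[object@counts == 0L] != 0)) {
    return("missing bins must contain exactly 0")
  }
  TRUE
})

#' StructuredModel: the hierarchy-constrained embedding network
#'
#' Each level-1 variable has an independent two-layer perceptron mapping its
#' binned sequence to one scalar embedding; each combo (and, for composite
#' models, each composite) has an independent sub-network over its members
#' only, so cross-group connections are structurally absent. A final linear
#' prediction layer maps the last embedding vector to two log-softmax outputs.
#'
#' @slot level One of `"base"`, `"combo"`, `"composite"`.
#' @slot strategy Grouping-strategy name (composite models only, else `NA`).
#' @slot taxonomy The [Taxonomy-class] the model was built against.
#' @slot nBins Number of input time bins per variable.
#' @slot hidden Hidden width of the per-variable embedding sub-network.
#' @slot params Nested list of weight arrays.
#' @slot seed Integer initialisation seed.
#' @export
setClass("StructuredModel", representation(
  level = "character",
  strategy = "character",
  taxonomy = "Taxonomy",
  nBins = "integer",
  hidden = "integer",
  params = "list",
  seed = "integer"
))

#' EmbeddingOutputs: all intermediate embeddings plus logits
#'
#' @slot level1 Patient x variable matrix of scalar variable embeddings.
#' @slot level2 Patient x combo matrix (combo/composite models; else 0 cols).
#' @slot level3 Patient x composite matrix (composite models; else 0 cols).
#' @slot logits Patient x 2 log-probabilities (columns `control`, `case`);
#'   each row exponentiates to a probability pair summing to one.
#' @export
setClass("EmbeddingOutputs", representation(
  level1 = "matrix",
  level2 = "matrix",
  level3 = "matrix",
  logits = "matrix"
))

setValidity("EmbeddingOutputs", function(object) {
  if (ncol(object@logits) != 2L) return("logits must have 2 columns")
  s <- rowLogSumExp(object@logits)
  if (any(abs(s) > 1e-6)) return("logit rows must log-sum-exp to 0")
  TRUE
})

#' ClusterContingency: cluster-by-class counts behind the total entropy
#'
#' @slot counts Integer matrix, clusters x class labels; entry (i, j) is the
#'   number of datapoints with class j assigned to cluster i.
#' @seealso [clusterContingency()], [totalEntropy()]
#' @export
setClass("ClusterContingency", representation(counts = "matrix"))

setValidity("ClusterContingency", function(object) {
  k <- object@counts
  if (length(k) == 0L) return("empty contingency")
  if (any(k < 0)) return("counts must be nonnegative")
  if (any(rowSums(k) == 0)) return("every retained cluster must be non-empty")
  TRUE
})
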