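#' @name accessors
#' @title Accessors for the core classes
#'
#' @description Small accessor generics; user code should use these rather
#'   than reaching into slots.
#'
#' @param x A [Taxonomy-class], [TensorizedCohort-class],
#'   [StructuredModel-class] or [EmbeddingOutputs-class] object.
#' @param strategy Strategy name where one is needed.
NULL

#' @rdname accessors
#' @export
setGeneric("taxVariables", function(x) standardGeneric("taxVariables"))
#' @rdname accessors
#' @export
setGeneric("taxCombos", function(x) standardGeneric("taxCombos"))
#' @rdname accessors
#' @export
setGeneric("comboMap", function(x) standardGeneric("comboMap"))
#' @rdname accessors
#' @export
setGeneric("strategyNames", function(x) standardGeneric("strategyNames"))
#' @rdname accessors
#' @export
setGeneric("strategyMap", function(x, strategy) standardGeneric("strategyMap"))
#' @rdname accessors
#' @export
setGeneric("composites", function(x, strategy) standardGeneric("composites"))
#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setGeneric("embeddingWidths", function(x) standardGeneric("embeddingWidths"))
#' @rdname accessors
#' @export
setGeneric("finalWidth", function(x) standardGeneric("finalWidth"))
#' @rdname accessors
#' @export
setGeneric("countParams", function(x) standardGeneric("countParams"))

#' @rdname accessors
#' @export
setMethod("taxVariables", "Taxonomy", function(x) x@variables)

#' @rdname accessors
#' @export
setMethod("taxCombos", "Taxonomy", function(x) unique(unname(x@comboMap[x@variables])))

#' @rdname accessors
#' @export
setMethod("comboMap", "Taxonomy", function(x) x@comboMap)

#' @rdname accessors
#' @export
setMethod("strategyNames", "Taxonomy", function(x) names(x@strategies))

#' @rdname accessors
#' @export
setMethod("strategyMap", "Taxonomy", function(x, strategy) {
  if (!strategy %in% names(x@strategies)) {
    stop(sprintf("unknown grouping strategy '%s' (have: %s)", strategy,
                 paste(names(x@strategies), collapse = ", ")))
  }
  x@strategies[[strategy]]
})

#' @rdname accessors
#' @export
setMethod("composites", "Taxonomy", function(x, strategy) {
  sm <- strategyMap(x, strategy)
  unique(unname(sm[taxCombos(x)]))
})

#' @rdname accessors
#' @export
setMethod("patientIds", "TensorizedCohort", function(x) dimnames(x@values)[[1L]])

#' @rdname accessors
#' @export
setMethod("taxVariables", "TensorizedCohort", function(x) dimnames(x@values)[[2L]])

#' @rdname accessors
#' @export
setMethod("gridValues", "TensorizedCohort", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("cohortLabels", "TensorizedCohort", function(x) x@labels)

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy: %d variables -> %d combos\n",
              length(object@variables), length(taxCombos(object))))
  for (s in names(object@strategies)) {
    cat(sprintf("  strategy '%s': %d composites\n", s,
                length(composites(object, s))))
  }
})

setMethod("show", "TensorizedCohort", function(object) {
  d <- dim(object@values)
  cat(sprintf(paste0("TensorizedCohort: %d patients x %d variables x %d bins ",
                     "(%.3g-month bins)\n"), d[1L], d[2L], d[3L],
              object@binWidthMonths))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels)), collapse = ", ")))
  if (sum(object@dropped) > 0) {
    cat(sprintf("  dropped records: %s\n",
                paste(sprintf("%s=%d", names(object@dropped), object@dropped),
                      collapse = ", ")))
  }
})

setMethod("show", "StructuredModel", function(object) {
  cat(sprintf("StructuredModel (level = %s%s): %d bins -> widths %s; %d parameters\n",
              object@level,
              if (is.na(object@strategy)) "" else paste0(", strategy = ", object@strategy),
              object@nBins,
              paste(embeddingWidths(object), collapse = " -> "),
              countParams(object)))
})

setMethod("show", "EmbeddingOutputs", function(object) {
  cat(sprintf("EmbeddingOutputs: %d patients; widths level1=%d level2=%d level3=%d\n",
              nrow(object@logits), ncol(object@level1), ncol(object@level2),
              ncol(object@level3)))
})

setMethod("show", "ClusterContingency", function(object) {
  cat(sprintf("ClusterContingency: %d clusters x %d classes, N = %d\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})
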