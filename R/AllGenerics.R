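#' @include AllClasses.R
NULL

#' Accessors for MotifSubtypes containers
#'
#' \code{sampleIDs} returns sample identifiers; \code{occurrence} and
#' \code{motifCounts} return the binary and integer assays of a
#' \linkS4class{GeneMotifExperiment}; \code{mutationRecords} and
#' \code{transcriptHits} return the deduplicated record table and the
#' per-transcript rows of a \linkS4class{MutationCohort};
#' \code{subtypeLabels} returns per-sample labels of a
#' \linkS4class{SubtypeTree}; \code{signatures} and \code{exposures}
#' return the factor matrices of a \linkS4class{SignatureSet};
#' \code{candidateFeatures} returns the clustering feature set of a
#' \linkS4class{SelectionResult}.
#'
#' @param x An object of the documented class.
#' @param relative For \code{exposures}: return column-normalised
#'   exposures instead of absolute loadings.
#' @return See the individual description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("occurrence", function(x) standardGeneric("occurrence"))

#' @rdname accessors
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))

#' @rdname accessors
#' @export
setGeneric("mutationRecords",
           function(x) standardGeneric("mutationRecords"))

#' @rdname accessors
#' @export
setGeneric("transcriptHits", function(x) standardGeneric("transcriptHits"))

#' @rdname accessors
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' @rdname accessors
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname accessors
#' @export
setGeneric("exposures",
           function(x, relative = FALSE) standardGeneric("exposures"))

#' @rdname accessors
#' @export
setGeneric("candidateFeatures",
           function(x) standardGeneric("candidateFeatures"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "MutationCohort", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "SummarizedExperiment", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "SubtypeTree", function(x) x@sampleIDs)

#' @rdname accessors
#' @export
setMethod("occurrence", "GeneMotifExperiment",
          function(x) assay(x, "occurrence"))

#' @rdname accessors
#' @export
setMethod("motifCounts", "GeneMotifExperiment",
          function(x) assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("motifCounts", "MotifCatalog", function(x) assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("mutationRecords", "MutationCohort", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("transcriptHits", "MutationCohort", function(x) x@transcriptHits)

#' @rdname accessors
#' @export
setMethod("subtypeLabels", "SubtypeTree",
          function(x) setNames(x@labels, x@sampleIDs))

#' @rdname accessors
#' @export
setMethod("signatures", "SignatureSet", function(x) x@signatures)

#' @rdname accessors
#' @export
setMethod("exposures", "SignatureSet", function(x, relative = FALSE) {
  if (relative) x@relativeExposures else x@exposures
})

#' @rdname accessors
#' @export
setMethod("candidateFeatures", "SelectionResult",
          function(x) x@candidateFeatures)

## ---------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------

setMethod("show", "MutationCohort", function(object) {
  cat("MutationCohort with", nrow(object@records),
      "deduplicated SNVs in", length(object@samples), "samples\n")
  cat("  genes observed:", length(object@genes), "\n")
  cat("  transcript rows:", nrow(object@transcriptHits), "\n")
  if (length(object@dropped) && sum(object@dropped) > 0) {
    cat("  dropped rows:",
        paste(names(object@dropped), object@dropped,
              sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (alpha =", object@alpha, ")\n")
  cat("  significant genes:", length(object@significantGenes),
      "(count >=", object@geneThreshold, ")\n")
  cat("  significant gene-motifs:", length(object@significantGeneMotifs),
      "(count >=", object@motifThreshold, ")\n")
  cat("  candidate clustering features:",
      length(object@candidateFeatures), "\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "GmmFit", function(object) {
  cat(sprintf("GmmFit: k = %d (%s), logLik = %.3f, BIC = %.3f\n",
              object@k, object@model, object@logLik, object@bic))
})

setMethod("show", "SubtypeTree", function(object) {
  tab <- table(object@labels)
  cat("SubtypeTree over", length(object@labels), "samples, minSize =",
      object@minSize, "\n")
  for (nm in names(sort(tab, decreasing = TRUE)))
    cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
})

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf(
    "SignatureSet: k = %d, mean silhouette = %.3f, recon. error = %.3f\n",
    object@k, object@meanSilhouette, object@reconstructionError))
})

setMethod("show", "KMCurve", function(object) {
  med <- if (is.na(object@median)) "not reached" else
    sprintf("%.2f", object@median)
  cat(sprintf(
    "KMCurve: n = %d, %d event times, median = %s, restricted mean = %.2f\n",
    object@n, length(object@time), med, object@restrictedMean))
})
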