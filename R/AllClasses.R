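#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
NULL

## ---------------------------------------------------------------------
## Mutation cohort
## ---------------------------------------------------------------------

#' Container for a deduplicated somatic SNV cohort
#'
#' Holds single-base substitution records deduplicated on
#' (sample, chrom, pos, ref, alt), the full per-transcript annotation
#' rows kept separately for transcript-level analyses, and bookkeeping
#' on rows dropped during cleaning.
#'
#' @slot records data.frame of deduplicated records with columns
#'   \code{sample_id, chrom, pos, ref, alt, gene_id, transcript_id,
#'   consequence}.
#' @slot transcriptHits data.frame mapping mutations to every
#'   overlapping transcript (one row per mutation x transcript).
#' @slot samples ordered unique sample identifiers.
#' @slot genes ordered unique gene identifiers observed in records.
#' @slot dropped named integer vector of dropped-row counts by reason.
#' @export
setClass("MutationCohort", slots = c(
  records = "data.frame",
  transcriptHits = "data.frame",
  samples = "character",
  genes = "character",
  dropped = "integer"
))

setValidity("MutationCohort", function(object) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt",
           "gene_id", "transcript_id", "consequence")
  if (!all(req %in% names(object@records)))
    return(paste("records must have columns:", paste(req, collapse = ", ")))
  r <- object@records
  if (nrow(r)) {
    if (!all(r$ref %in% BASES) || !all(r$alt %in% BASES))
      return("ref/alt must be single bases in A,C,G,T")
    if (any(r$ref == r$alt)) return("ref must differ from alt")
    if (any(r$pos < 1)) return("positions must be >= 1")
    key <- paste(r$sample_id, r$chrom, r$pos, r$ref, r$alt)
    if (anyDuplicated(key))
      return("records contain duplicated (sample, locus, alleles)")
    if (!all(r$sample_id %in% object@samples))
      return("records reference samples missing from @samples")
  }
  TRUE
})

## ---------------------------------------------------------------------
## Gene-motif occurrence matrix (features x samples, SE-backed)
## ---------------------------------------------------------------------

#' Gene-motif occurrence matrix
#'
#' A \linkS4class{SummarizedExperiment} with gene-motif features as rows
#' and samples as columns, carrying two parallel assays: integer
#' mutation \code{counts} and the derived binary \code{occurrence}
#' (counts >= 1). \code{rowData} stores the gene and motif class of
#' every feature; feature order is lexicographic in the label.
#'
#' @export
setClass("GeneMotifExperiment", contains = "SummarizedExperiment")

setValidity("GeneMotifExperiment", function(object) {
  if (!all(c("counts", "occurrence") %in% names(assays(object))))
    return("assays 'counts' and 'occurrence' are required")
  if (!all(c("gene", "motif") %in% names(rowData(object))))
    return("rowData must carry 'gene' and 'motif'")
  cnt <- assay(object, "counts")
  occ <- assay(object, "occurrence")
  if (!identical(dim(cnt), dim(occ)))
    return("counts and occurrence must have identical dimensions")
  if (nrow(cnt) && !identical(unname(occ), unname((cnt >= 1L) * 1L)) &&
      !isTRUE(all.equal(unname(occ), unname((cnt >= 1L) * 1L))))
    return("occurrence must equal (counts >= 1)")
  TRUE
})

## ---------------------------------------------------------------------
## 96-class catalog matrix (classes x samples, SE-backed)
## ---------------------------------------------------------------------

#' 96-class substitution catalog
#'
#' A \linkS4class{SummarizedExperiment} with the 96 canonical motif
#' classes as rows (fixed order, see \code{\link{motifClassLabels}})
#' and samples as columns; the single assay \code{counts} holds integer
#' mutation counts. \code{metadata(x)$skipped} records, per sample, the
#' number of deduplicated SNVs excluded for unusable context.
#'
#' @export
setClass("MotifCatalog", contains = "SummarizedExperiment")

setValidity("MotifCatalog", function(object) {
  if (nrow(object) != 96L) return("a MotifCatalog must have 96 rows")
  if (!identical(rownames(object), motifClassLabels()))
    return("rows must be the 96 motif classes in canonical order")
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  TRUE
})

## ---------------------------------------------------------------------
## Feature selection result
## ---------------------------------------------------------------------

#' Result of empirical top-tail feature selection
#'
#' @slot geneThreshold smallest mutated-sample count at which a gene is
#'   significant.
#' @slot motifThreshold smallest occurrence count at which a gene-motif
#'   is significant.
#' @slot significantGenes,significantGeneMotifs character vectors.
#' @slot candidateFeatures significant gene-motifs whose gene is itself
#'   significant; the clustering feature set, lexicographically ordered.
#' @slot alpha tail probability used (default 0.01).
#' @slot denominators named integer vector (genes, gene_motifs).
#' @slot flags character vector of degenerate-case flags.
#' @export
setClass("SelectionResult", slots = c(
  geneThreshold = "numeric",
  motifThreshold = "numeric",
  significantGenes = "character",
  significantGeneMotifs = "character",
  candidateFeatures = "character",
  alpha = "numeric",
  denominators = "integer",
  flags = "character"
))

setValidity("SelectionResult", function(object) {
  if (!all(object@candidateFeatures %in% object@significantGeneMotifs))
    return("candidate features must be significant gene-motifs")
  genes <- splitGeneMotif(object@candidateFeatures)$gene
  if (length(genes) && !all(genes %in% object@significantGenes))
    return("candidate features must belong to significant genes")
  TRUE
})

## ---------------------------------------------------------------------
## Gaussian mixture fit
## ---------------------------------------------------------------------

#' A fitted diagonal/spherical Gaussian mixture
#'
#' @slot k number of components.
#' @slot means k x d matrix of component means.
#' @slot variances k x d matrix of per-dimension variances (floored).
#' @slot weights mixing proportions (sum to 1).
#' @slot logLik maximised log-likelihood.
#' @slot nParams free parameter count.
#' @slot bic 2*logLik - nParams*log(n) (maximised-form BIC).
#' @slot responsibilities n x k posterior membership matrix.
#' @slot classification hard assignment (argmax responsibility).
#' @slot model covariance family, "diagonal" or "spherical".
#' @slot converged logical.
#' @export
setClass("GmmFit", slots = c(
  k = "integer", means = "matrix", variances = "matrix",
  weights = "numeric", logLik = "numeric", nParams = "integer",
  bic = "numeric", responsibilities = "matrix",
  classification = "integer", model = "character",
  converged = "logical"
))

setValidity("GmmFit", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-6)
    return("component weights must sum to 1")
  if (any(object@variances <= 0))
    return("variances must be positive")
  TRUE
})

## ---------------------------------------------------------------------
## Recursive clustering result
## ---------------------------------------------------------------------

#' Recursive model-based clustering tree
#'
#' @slot labels per-sample subtype label (\code{"PCS1"}, ... in
#'   decreasing leaf-size order) or \code{"OUTLIER"}.
#' @slot sampleIDs sample identifiers, parallel to labels.
#' @slot nodes list of per-node records (sample index set, chosen k,
#'   BIC table, depth, status).
#' @slot minSize the meaningful-cluster size threshold used.
#' @export
setClass("SubtypeTree", slots = c(
  labels = "character",
  sampleIDs = "character",
  nodes = "list",
  minSize = "integer"
))

setValidity("SubtypeTree", function(object) {
  if (length(object@labels) != length(object@sampleIDs))
    return("labels and sampleIDs must be parallel")
  tab <- table(object@labels[object@labels != "OUTLIER"])
  ## a cohort smaller than minSize is returned whole as one leaf
  wholeCohort <- length(tab) == 1L &&
    tab[[1L]] == length(object@labels)
  if (length(tab) && !wholeCohort && any(tab < object@minSize))
    return("every leaf must hold at least minSize samples")
  TRUE
})

## ---------------------------------------------------------------------
## Signature set
## ---------------------------------------------------------------------

#' A set of deciphered mutational signatures with exposures
#'
#' @slot signatures 96 x k column-stochastic matrix (rows in canonical
#'   class order).
#' @slot exposures k x samples nonnegative absolute exposures.
#' @slot relativeExposures column-normalised exposures.
#' @slot silhouette per-signature mean silhouette width (cosine
#'   distance) from the bootstrap clustering.
#' @slot meanSilhouette mean of slot silhouette.
#' @slot reconstructionError Frobenius norm of M - W H.
#' @slot k number of signatures.
#' @export
setClass("SignatureSet", slots = c(
  signatures = "matrix",
  exposures = "matrix",
  relativeExposures = "matrix",
  silhouette = "numeric",
  meanSilhouette = "numeric",
  reconstructionError = "numeric",
  k = "integer"
))

setValidity("SignatureSet", function(object) {
  W <- object@signatures
  if (nrow(W) != 96L) return("signatures must have 96 rows")
  cs <- colSums(W)
  if (any(abs(cs - 1) > 1e-6)) return("signature columns must sum to 1")
  if (any(W < 0)) return("signatures must be nonnegative")
  if (length(object@silhouette) &&
      any(object@silhouette < -1 - 1e-9 | object@silhouette > 1 + 1e-9))
    return("silhouette values must lie in [-1, 1]")
  TRUE
})

## ---------------------------------------------------------------------
## Kaplan-Meier curve
## ---------------------------------------------------------------------

#' Product-limit survival estimate for one group
#'
#' @slot time distinct observed times (increasing).
#' @slot survival step values of the product-limit estimate.
#' @slot nRisk,nEvent,nCensor integer series at each time.
#' @slot lower,upper Greenwood log-log 95 percent confidence bounds.
#' @slot median earliest time with survival <= 0.5 (NA if never).
#' @slot restrictedMean area under the curve up to the largest
#'   observed time.
#' @slot n number of subjects.
#' @export
setClass("KMCurve", slots = c(
  time = "numeric", survival = "numeric",
  nRisk = "integer", nEvent = "integer", nCensor = "integer",
  lower = "numeric", upper = "numeric",
  median = "numeric", restrictedMean = "numeric", n = "integer"
))

setValidity("KMCurve", function(object) {
  if (is.unsorted(object@time)) return("times must be increasing")
  s <- object@survival
  if (length(s) && (any(diff(s) > 1e-12) || any(s < -1e-12 | s > 1 + 1e-12)))
    return("survival must be non-increasing within [0,1]")
  TRUE
})
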