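#' Empirical top-tail count threshold
#'
#' Given per-item occurrence counts, returns the smallest count
#' \code{c*} such that the fraction of items (relative to
#' \code{denominator}) with count >= \code{c*} is at most \code{alpha}.
#' Items tied at the threshold are all included. If no such count
#' exists (massive ties), \code{max(counts) + 1} is returned and the
#' selection is empty; callers see this through attribute
#' \code{"empty"}.
#'
#' @param counts Integer vector of per-item counts (named or not).
#' @param denominator Item-universe size; must be at least the number
#'   of items with a positive count.
#' @param alpha Tail probability in (0, 1]; 1 is the vacuous threshold
#'   keeping every observed item.
#' @return Integer threshold with attribute \code{empty} (logical).
#' @examples
#' tailThreshold(c(10, rep(1, 99)), denominator = 100, alpha = 0.01)
#' @export
tailThreshold <- function(counts, denominator, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
      alpha > 1)
    stop("alpha must lie in (0, 1]")
  counts <- as.numeric(counts)
  if (denominator < sum(counts > 0))
    stop("denominator smaller than the number of occurring items")
  if (!length(counts)) {
    out <- 1L; attr(out, "empty") <- TRUE
    return(out)
  }
  sorted <- sort(unique(counts))
  for (c0 in sorted) {
    if (sum(counts >= c0) / denominator <= alpha) {
      out <- c0
      attr(out, "empty") <- FALSE
      return(out)
    }
  }
  out <- max(counts) + 1
  attr(out, "empty") <- TRUE
  out
}

#' Select significant genes and gene-motifs for clustering
#'
#' Applies \code{\link{tailThreshold}} separately to per-gene
#' mutated-sample counts and per-gene-motif occurrence counts; the
#' clustering features are the significant gene-motifs whose gene is
#' itself significant.
#'
#' The gene denominator defaults to the size of the gene universe
#' (e.g. all annotated genes); the gene-motif denominator defaults to
#' the number of observed (count >= 1) gene-motifs. Both are
#' overridable.
#'
#' @param geneMotifs A \linkS4class{GeneMotifExperiment}.
#' @param genePresence Named integer vector: per-gene number of samples
#'   carrying at least one mutation in the gene (computed with
#'   \code{\link{genePresenceCounts}}).
#' @param alpha Tail probability (default 0.01).
#' @param geneDenominator,motifDenominator Optional denominators.
#' @return A \linkS4class{SelectionResult}.
#' @export
selectFeatures <- function(geneMotifs, genePresence, alpha = 0.01,
                           geneDenominator = NULL,
                           motifDenominator = NULL) {
  stopifnot(methods::is(geneMotifs, "GeneMotifExperiment"))
  occ <- occurrence(geneMotifs)
  motifCountsPerFeature <- rowSums(occ)   # samples per gene-motif
  if (is.null(geneDenominator)) geneDenominator <- length(genePresence)
  if (is.null(motifDenominator))
    motifDenominator <- sum(motifCountsPerFeature >= 1)
  flags <- character(0)

  gThr <- tailThreshold(genePresence, geneDenominator, alpha)
  if (attr(gThr, "empty")) flags <- c(flags, "empty_gene_selection")
  mThr <- tailThreshold(motifCountsPerFeature, motifDenominator, alpha)
  if (attr(mThr, "empty")) flags <- c(flags, "empty_motif_selection")

  sigGenes <- names(genePresence)[genePresence >= as.numeric(gThr)]
  sigMotifs <- rownames(occ)[motifCountsPerFeature >= as.numeric(mThr)]
  featGene <- rowData(geneMotifs)$gene[
    match(sigMotifs, rownames(occ))]
  candidates <- sort(sigMotifs[featGene %in% sigGenes])

  methods::new("SelectionResult",
    geneThreshold = as.numeric(gThr),
    motifThreshold = as.numeric(mThr),
    significantGenes = sort(sigGenes),
    significantGeneMotifs = sort(sigMotifs),
    candidateFeatures = candidates,
    alpha = alpha,
    denominators = c(genes = as.integer(geneDenominator),
                     gene_motifs = as.integer(motifDenominator)),
    flags = flags)
}

#' Per-gene mutated-sample counts
#'
#' Number of distinct samples carrying at least one deduplicated SNV in
#' each gene. Genes present in \code{universe} but never mutated get a
#' zero count, so the empirical distribution covers the whole gene
#' universe.
#'
#' @param cohort A \linkS4class{MutationCohort}.
#' @param universe Optional character vector of gene IDs (e.g. all
#'   annotated genes).
#' @return Named integer vector.
#' @export
genePresenceCounts <- function(cohort, universe = NULL) {
  rec <- cohort@records
  rec <- rec[rec$gene_id != "", c("sample_id", "gene_id")]
  rec <- unique(rec)
  counts <- table(rec$gene_id)
  if (is.null(universe)) universe <- sort(unique(rec$gene_id))
  out <- setNames(integer(length(universe)), universe)
  hit <- intersect(names(counts), universe)
  out[hit] <- as.integer(counts[hit])
  out
}
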