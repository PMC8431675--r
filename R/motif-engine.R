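#' @importFrom Biostrings readDNAStringSet DNAStringSet
NULL

normalizeChrom <- function(x) sub("^chr", "", as.character(x))

## Accept a DNAStringSet or a FASTA path; return a named character
## vector of uppercase chromosome sequences with normalized names.
referenceAsStrings <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- toupper(as.character(reference))
  } else if (is.character(reference) && !is.null(names(reference))) {
    seqs <- toupper(reference)
  } else {
    stop("reference must be a DNAStringSet, a named character vector, ",
         "or a FASTA path")
  }
  ## FASTA headers may carry descriptions after whitespace
  names(seqs) <- normalizeChrom(sub("\\s.*$", "", names(seqs)))
  seqs
}

#' Extract the trinucleotide context of genomic positions
#'
#' Reads the immediate 5' and 3' flanking bases of 1-based positions
#' from the "+" strand of the reference. Positions at a sequence
#' boundary, or whose triplet contains a non-ACGT character, are
#' flagged unusable.
#'
#' @param reference A \code{DNAStringSet}, named character vector of
#'   sequences, or FASTA path.
#' @param chrom Character vector of chromosome names (a leading
#'   \code{"chr"} is ignored for matching).
#' @param pos Integer vector of 1-based positions.
#' @return data.frame with columns \code{left}, \code{ref},
#'   \code{right}, \code{usable}.
#' @examples
#' extractContext(c(chr1 = "GACT"), "chr1", 2)  # G . C, usable
#' @export
extractContext <- function(reference, chrom, pos) {
  seqs <- referenceAsStrings(reference)
  chrom <- normalizeChrom(chrom)
  pos <- as.integer(pos)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  unknown <- !(chrom %in% names(seqs))
  if (any(unknown))
    stop("unknown chromosome(s): ",
         paste(unique(chrom[unknown]), collapse = ", "))
  len <- nchar(seqs)[chrom]
  if (any(pos < 1L | pos > len))
    stop("position outside [1, chromosome length]")
  left <- ref <- right <- rep(NA_character_, n)
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    s <- seqs[[cn]]; L <- nchar(s)
    p <- pos[i]
    ref[i] <- substring(s, p, p)
    hasL <- p > 1L; hasR <- p < L
    if (any(hasL))
      left[i][hasL] <- substring(s, p[hasL] - 1L, p[hasL] - 1L)
    if (any(hasR))
      right[i][hasR] <- substring(s, p[hasR] + 1L, p[hasR] + 1L)
  }
  usable <- !is.na(left) & !is.na(right) &
    left %in% BASES & right %in% BASES & ref %in% BASES
  data.frame(left = left, ref = ref, right = right, usable = usable,
             stringsAsFactors = FALSE)
}

## Shared worker: canonical class index per deduplicated record, with
## NA for unusable context or reference-mismatch; warns on mismatches.
.recordClasses <- function(records, seqs, strict = FALSE) {
  n <- nrow(records)
  if (n == 0L) {
    return(list(class = integer(0), skipped = logical(0),
                mismatch = logical(0)))
  }
  ctx <- extractContext(seqs, records$chrom, records$pos)
  mismatch <- ctx$usable & ctx$ref != records$ref
  ## also catch mismatches at unusable positions where ref is readable
  mismatch <- mismatch | (!is.na(ctx$ref) & ctx$ref %in% BASES &
                            ctx$ref != records$ref)
  if (any(mismatch)) {
    msg <- sprintf(
      "%d record(s) disagree with the reference base and were excluded",
      sum(mismatch))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  ok <- ctx$usable & !mismatch
  cls <- rep(NA_integer_, n)
  if (any(ok)) {
    lab <- canonicalizeMotif(records$ref[ok], records$alt[ok],
                             ctx$left[ok], ctx$right[ok])
    cls[ok] <- match(lab, motifClassLabels())
  }
  list(class = cls, skipped = !ok, mismatch = mismatch)
}

#' Build the binary samples-by-gene-motif occurrence matrix
#'
#' For every deduplicated mutation carrying a gene assignment, the
#' canonical motif class is derived from the reference context and
#' concatenated with the gene into a gene-motif feature. Mutations
#' without a gene, with unusable context, or disagreeing with the
#' reference base contribute to no feature.
#'
#' @param cohort A \linkS4class{MutationCohort}.
#' @param reference Reference sequences (see
#'   \code{\link{extractContext}}).
#' @param strict Error (rather than warn) on reference-base
#'   disagreement.
#' @return A \linkS4class{GeneMotifExperiment} (features x samples)
#'   with assays \code{counts} and \code{occurrence}.
#' @export
buildGeneMotifMatrix <- function(cohort, reference, strict = FALSE) {
  stopifnot(methods::is(cohort, "MutationCohort"))
  seqs <- referenceAsStrings(reference)
  rec <- cohort@records
  samples <- cohort@samples
  res <- .recordClasses(rec, seqs, strict = strict)
  genic <- !is.na(rec$gene_id) & rec$gene_id != "" & !res$skipped
  lab <- character(0); samp <- character(0)
  if (any(genic)) {
    lab <- geneMotifLabel(rec$gene_id[genic],
                          motifClassLabels()[res$class[genic]])
    samp <- rec$sample_id[genic]
  }
  feats <- sort(unique(lab))
  cnt <- matrix(0L, nrow = length(feats), ncol = length(samples),
                dimnames = list(feats, samples))
  if (length(lab)) {
    t3 <- table(factor(lab, levels = feats),
                factor(samp, levels = samples))
    cnt[] <- as.integer(t3)
  }
  parts <- if (length(feats)) splitGeneMotif(feats) else
    data.frame(gene = character(0), motif = character(0))
  se <- SummarizedExperiment(
    assays = SimpleList(counts = cnt, occurrence = (cnt >= 1L) * 1L),
    rowData = DataFrame(gene = parts$gene, motif = parts$motif))
  metadata(se)$excluded <- c(
    no_gene = sum((is.na(rec$gene_id) | rec$gene_id == "") & !res$skipped),
    unusable_context = sum(res$skipped & !res$mismatch),
    reference_mismatch = sum(res$mismatch))
  methods::new("GeneMotifExperiment", se)
}

#' Build the 96-class catalog matrix
#'
#' Aggregates all deduplicated SNVs of each sample (genic and
#' intergenic by default) into counts over the 96 canonical motif
#' classes.
#'
#' @inheritParams buildGeneMotifMatrix
#' @param genicOnly Restrict to mutations carrying a gene assignment.
#' @return A \linkS4class{MotifCatalog} (96 x samples);
#'   \code{metadata()$skipped} counts context-skipped mutations per
#'   sample.
#' @export
buildCatalogMatrix <- function(cohort, reference, genicOnly = FALSE,
                               strict = FALSE) {
  stopifnot(methods::is(cohort, "MutationCohort"))
  seqs <- referenceAsStrings(reference)
  rec <- cohort@records
  if (genicOnly)
    rec <- rec[!is.na(rec$gene_id) & rec$gene_id != "", , drop = FALSE]
  samples <- cohort@samples
  res <- .recordClasses(rec, seqs, strict = strict)
  keep <- !res$skipped
  cnt <- matrix(0L, nrow = 96L, ncol = length(samples),
                dimnames = list(motifClassLabels(), samples))
  if (any(keep)) {
    t3 <- table(factor(res$class[keep], levels = seq_len(96L)),
                factor(rec$sample_id[keep], levels = samples))
    cnt[] <- as.integer(t3)
  }
  skipped <- table(factor(rec$sample_id[res$skipped], levels = samples))
  se <- SummarizedExperiment(assays = SimpleList(counts = cnt))
  metadata(se)$skipped <- setNames(as.integer(skipped), samples)
  methods::new("MotifCatalog", se)
}

#' Relative 96-class frequency profile over a sample subset
#'
#' Sums class counts over the requested samples and normalises to sum
#' one. An all-zero subset yields a zero vector with attribute
#' \code{empty = TRUE}.
#'
#' @param catalog A \linkS4class{MotifCatalog}.
#' @param samples Character vector of sample IDs (default: all).
#' @return Named numeric vector of length 96.
#' @export
motifProfile <- function(catalog, samples = NULL) {
  stopifnot(methods::is(catalog, "MotifCatalog"))
  cnt <- assay(catalog, "counts")
  if (is.null(samples)) samples <- colnames(cnt)
  missing <- setdiff(samples, colnames(cnt))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  v <- rowSums(cnt[, samples, drop = FALSE])
  tot <- sum(v)
  if (tot == 0) {
    out <- setNames(rep(0, 96L), rownames(cnt))
    attr(out, "empty") <- TRUE
    return(out)
  }
  v / tot
}
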