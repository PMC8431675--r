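#' @importFrom utils read.delim write.table
NULL

## column synonyms accepted in ICGC-style SSM tables
.ssmCols <- list(
  sample_id = c("icgc_donor_id", "sample_id", "donor_id"),
  chrom = c("chromosome", "chrom", "chr"),
  pos = c("chromosome_start", "pos", "position", "start"),
  ref = c("reference_genome_allele", "ref", "reference_allele"),
  alt = c("mutated_to_allele", "alt", "tumor_allele"),
  gene_id = c("gene_affected", "gene_id", "gene"),
  transcript_id = c("transcript_affected", "transcript_id", "transcript"),
  consequence = c("consequence_type", "consequence")
)

.pickCol <- function(df, synonyms, required = TRUE, what = synonyms[1]) {
  hit <- intersect(synonyms, names(df))
  if (!length(hit)) {
    if (required)
      stop("SSM table is missing required column '", what, "'")
    return(NULL)
  }
  df[[hit[1]]]
}

#' Assemble a MutationCohort from raw substitution rows
#'
#' Applies the cleaning rules used throughout the package: rows whose
#' alleles are not single A/C/G/T bases (or where ref equals alt) are
#' dropped and counted; surviving rows are deduplicated on
#' (sample, chrom, pos, ref, alt), keeping the first row's consequence,
#' while the full per-transcript row list is retained separately for
#' transcript-level analyses.
#'
#' @param df data.frame with columns \code{sample_id, chrom, pos, ref,
#'   alt} and optionally \code{gene_id, transcript_id, consequence}.
#' @return A \linkS4class{MutationCohort}.
#' @export
makeMutationCohort <- function(df) {
  for (cc in c("gene_id", "transcript_id", "consequence"))
    if (is.null(df[[cc]])) df[[cc]] <- rep("", nrow(df))
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- normalizeChrom(df$chrom)
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  blankNA <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }
  df$gene_id <- blankNA(df$gene_id)
  df$transcript_id <- blankNA(df$transcript_id)
  df$consequence <- blankNA(df$consequence)

  snv <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt &
    !is.na(df$pos) & df$pos >= 1L
  dropped <- c(non_snv = sum(!snv))
  df <- df[snv, , drop = FALSE]

  keep <- c("sample_id", "chrom", "pos", "ref", "alt",
            "gene_id", "transcript_id", "consequence")
  df <- df[, keep, drop = FALSE]

  key <- paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt,
               sep = "\r")
  first <- !duplicated(key)
  records <- df[first, , drop = FALSE]
  rownames(records) <- NULL
  hits <- df[df$transcript_id != "", , drop = FALSE]
  rownames(hits) <- NULL

  methods::new("MutationCohort",
    records = records,
    transcriptHits = hits,
    samples = sort(unique(df$sample_id)),
    genes = sort(unique(records$gene_id[records$gene_id != ""])),
    dropped = dropped)
}

#' Read a simple somatic mutation catalog
#'
#' Supports ICGC-style SSM tab-separated tables (one row per mutation
#' per annotated transcript) and VCF v4. Only single-nucleotide
#' substitutions with A/C/G/T alleles are retained; multi-base or
#' ambiguous rows are dropped with a logged count. Records are
#' deduplicated on (sample, chrom, pos, ref, alt); the transcript-level
#' rows are kept for transcript analyses.
#'
#' @param path File path.
#' @param format \code{"icgc_tsv"} or \code{"vcf"}.
#' @param sampleID Sample identifier to assign to VCF records lacking a
#'   per-record sample annotation (default \code{"sample1"}).
#' @return A \linkS4class{MutationCohort}.
#' @export
readSSM <- function(path, format = c("icgc_tsv", "vcf"),
                    sampleID = "sample1") {
  format <- match.arg(format)
  if (format == "icgc_tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     check.names = FALSE, colClasses = "character")
    if (nrow(df) == 0L) stop("empty SSM file: ", path)
    raw <- data.frame(
      sample_id = .pickCol(df, .ssmCols$sample_id, what = "icgc_donor_id"),
      chrom = .pickCol(df, .ssmCols$chrom, what = "chromosome"),
      pos = .pickCol(df, .ssmCols$pos, what = "chromosome_start"),
      ref = .pickCol(df, .ssmCols$ref, what = "reference_genome_allele"),
      alt = .pickCol(df, .ssmCols$alt, what = "mutated_to_allele"),
      stringsAsFactors = FALSE)
    for (cc in c("gene_id", "transcript_id", "consequence")) {
      v <- .pickCol(df, .ssmCols[[cc]], required = FALSE)
      raw[[cc]] <- if (is.null(v)) "" else v
    }
  } else {
    raw <- .readVcfMinimal(path, sampleID = sampleID)
    if (nrow(raw) == 0L) stop("empty VCF: ", path)
  }
  makeMutationCohort(raw)
}

## Minimal biallelic-SNV view of a VCF. Tries VariantAnnotation when
## available; otherwise falls back to a plain-text scan of the
## mandatory first eight columns.
.readVcfMinimal <- function(path, sampleID = "sample1") {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- VariantAnnotation::alt(vcf)
    altChar <- vapply(as.list(alt), function(a)
      if (length(a)) as.character(a[[1]]) else "", "")
    return(data.frame(
      sample_id = sampleID,
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = altChar,
      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  short <- vapply(parts, length, 0L) < 5L
  if (any(short)) stop("malformed VCF data line(s) in ", path)
  data.frame(
    sample_id = sampleID,
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 4L),
    alt = vapply(parts, `[`, "", 5L),
    stringsAsFactors = FALSE)
}

#' Read a gene/transcript annotation table
#'
#' Expects a tab-separated file with one row per transcript and columns
#' \code{gene_id, transcript_id, chrom, start, end, strand} (1-based
#' inclusive coordinates) plus optional \code{gene_start, gene_end}
#' giving the enclosing gene interval (otherwise the gene interval is
#' the span of its transcripts).
#'
#' @param path File path or data.frame.
#' @return A list with \code{genes} and \code{transcripts}, both
#'   \code{GRanges} carrying \code{gene_id} (and \code{transcript_id}).
#' @export
readAnnotation <- function(path) {
  df <- if (is.data.frame(path)) path else
    read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  df$chrom <- normalizeChrom(df$chrom)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end)))
    stop("annotation has non-numeric coordinates")
  if (any(df$start > df$end))
    stop("annotation rows with start > end")

  if (!all(c("gene_start", "gene_end") %in% names(df))) {
    gs <- tapply(df$start, df$gene_id, min)
    ge <- tapply(df$end, df$gene_id, max)
    df$gene_start <- as.integer(gs[df$gene_id])
    df$gene_end <- as.integer(ge[df$gene_id])
  }
  ## per-gene consistency
  bygene <- split(df, df$gene_id)
  for (g in names(bygene)) {
    b <- bygene[[g]]
    if (length(unique(b$chrom)) > 1L ||
        length(unique(b$gene_start)) > 1L ||
        length(unique(b$gene_end)) > 1L)
      stop("gene '", g, "' has inconsistent (duplicate) intervals")
    if (any(b$start < b$gene_start | b$end > b$gene_end))
      stop("transcript interval outside gene '", g, "'")
    if (anyDuplicated(b$transcript_id))
      stop("gene '", g, "' has duplicated transcript IDs")
  }
  geneDf <- unique(df[, c("gene_id", "chrom", "gene_start",
                          "gene_end", "strand")])
  genes <- GenomicRanges::GRanges(
    seqnames = geneDf$chrom,
    ranges = IRanges::IRanges(geneDf$gene_start, geneDf$gene_end),
    strand = geneDf$strand, gene_id = geneDf$gene_id)
  transcripts <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, gene_id = df$gene_id,
    transcript_id = df$transcript_id)
  list(genes = genes, transcripts = transcripts)
}

#' Read a clinical table
#'
#' Permissive reader: all rows are returned and malformed numeric
#' fields become missing. A \code{survival_eligible} flag is FALSE
#' exactly when survival time is missing or zero, or vital status is
#' missing - the exclusion rule applied before survival analysis.
#'
#' @param path File path or data.frame.
#' @return data.frame with columns \code{sample_id, sex, project_code,
#'   survival_time, vital_status, stage, grade, survival_eligible}.
#' @export
readClinical <- function(path) {
  df <- if (is.data.frame(path)) path else
    read.delim(path, stringsAsFactors = FALSE,
               colClasses = "character")
  syn <- list(
    sample_id = c("sample_id", "icgc_donor_id", "donor_id"),
    sex = c("sex", "donor_sex", "gender"),
    project_code = c("project_code", "project"),
    survival_time = c("survival_time", "donor_survival_time"),
    vital_status = c("vital_status", "donor_vital_status"),
    stage = c("stage", "tumour_stage", "tumor_stage"),
    grade = c("grade", "tumour_grade", "tumor_grade"))
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (cc in names(syn)) {
    v <- .pickCol(df, syn[[cc]], required = cc %in% c("sample_id"),
                  what = cc)
    out[[cc]] <- if (is.null(v)) NA else v
  }
  out$sample_id <- as.character(out$sample_id)
  out$sex <- tolower(as.character(out$sex))
  out$sex[!(out$sex %in% c("male", "female"))] <- "unknown"
  out$survival_time <- suppressWarnings(as.numeric(out$survival_time))
  out$vital_status <- tolower(as.character(out$vital_status))
  out$vital_status[!(out$vital_status %in% c("deceased", "alive"))] <-
    "missing"
  out$survival_eligible <- !is.na(out$survival_time) &
    out$survival_time > 0 & out$vital_status != "missing"
  out
}

#' Read a reference signature catalog (96 x K)
#'
#' The first column must hold the 96 motif-class labels in either the
#' native \code{"CT-G.A"} notation or COSMIC \code{"G[C>T]A"} notation
#' (auto-detected); remaining columns are signature profiles. Rows are
#' reordered to the package's fixed class order and columns are
#' renormalised to sum to one.
#'
#' @param path File path.
#' @return Numeric matrix, 96 rows (canonical order) x K signatures.
#' @export
readSignatureCatalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 96L)
    stop("signature catalog must have exactly 96 rows, found ", nrow(df))
  labs <- as.character(df[[1]])
  if (all(grepl("^[ACGT]\\[[ACGT]>[ACGT]\\][ACGT]$", labs))) {
    labs <- cosmicToNative(labs)
  } else if (!all(grepl("^[ACGT][ACGT]-[ACGT]\\.[ACGT]$", labs))) {
    bad <- labs[!grepl("^[ACGT][ACGT]-[ACGT]\\.[ACGT]$", labs)]
    stop("unrecognised motif labels, e.g.: ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  if (anyDuplicated(labs) || !setequal(labs, motifClassLabels()))
    stop("signature catalog labels do not cover the 96 classes")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- labs
  m <- m[motifClassLabels(), , drop = FALSE]
  cs <- colSums(m)
  if (any(cs <= 0)) stop("signature catalog has a non-positive column")
  sweep(m, 2, cs, "/")
}

#' Assign genes to mutations by interval overlap
#'
#' For records lacking a \code{gene_id} (e.g. read from VCF), assigns
#' the gene whose interval covers the position; records overlapping no
#' gene stay unassigned. When a record overlaps several genes the
#' first by annotation order is taken.
#'
#' @param cohort A \linkS4class{MutationCohort}.
#' @param annotation Result of \code{\link{readAnnotation}}.
#' @return The cohort with gene assignments filled in.
#' @export
assignGenes <- function(cohort, annotation) {
  rec <- cohort@records
  todo <- which(is.na(rec$gene_id) | rec$gene_id == "")
  if (!length(todo)) return(cohort)
  gr <- GenomicRanges::GRanges(
    seqnames = rec$chrom[todo],
    ranges = IRanges::IRanges(rec$pos[todo], rec$pos[todo]))
  hits <- GenomicRanges::findOverlaps(gr, annotation$genes,
                                      select = "first")
  has <- !is.na(hits)
  rec$gene_id[todo[has]] <-
    annotation$genes$gene_id[hits[has]]
  methods::initialize(cohort, records = rec,
    genes = sort(unique(rec$gene_id[rec$gene_id != ""])))
}
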