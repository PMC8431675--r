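makeSsmFile <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("ICGC rows deduplicate per locus while keeping transcript rows", {
  df <- data.frame(
    icgc_donor_id = "d1", chromosome = "1",
    chromosome_start = 100L, chromosome_end = 100L,
    reference_genome_allele = "C", mutated_to_allele = "T",
    gene_affected = "g1",
    transcript_affected = c("t1", "t2", "t3"),
    consequence_type = c("missense", "synonymous", "intron"))
  cohort <- readSSM(makeSsmFile(df), "icgc_tsv")
  expect_identical(nrow(mutationRecords(cohort)), 1L)
  expect_identical(nrow(transcriptHits(cohort)), 3L)
  ## first row's consequence is retained
  expect_identical(mutationRecords(cohort)$consequence, "missense")
})

test_that("non-SNV rows are dropped and counted", {
  df <- data.frame(
    icgc_donor_id = "d1", chromosome = "1",
    chromosome_start = c(100L, 200L, 300L),
    chromosome_end = c(100L, 201L, 300L),
    reference_genome_allele = c("C", "AT", "N"),
    mutated_to_allele = c("T", "G", "A"),
    gene_affected = "g1", transcript_affected = "t1",
    consequence_type = "missense")
  cohort <- readSSM(makeSsmFile(df), "icgc_tsv")
  expect_identical(nrow(mutationRecords(cohort)), 1L)
  expect_identical(unname(cohort@dropped["non_snv"]), 2L)
})

test_that("missing required SSM columns are reported by name", {
  df <- data.frame(icgc_donor_id = "d1", chromosome = "1",
                   chromosome_start = 1L,
                   mutated_to_allele = "T")
  expect_error(readSSM(makeSsmFile(df), "icgc_tsv"),
               "reference_genome_allele")
  empty <- tempfile(fileext = ".tsv")
  writeLines(paste("icgc_donor_id", "chromosome", "chromosome_start",
                   "reference_genome_allele", "mutated_to_allele",
                   sep = "\t"), empty)
  expect_error(readSSM(empty, "icgc_tsv"), "empty")
})

test_that("minimal VCF lines map onto mutation records", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", sep = "\t"),
    paste("chr1", "100", ".", "C", "T", ".", ".", ".", sep = "\t"),
    paste("chr1", "200", ".", "CT", "C", ".", ".", ".", sep = "\t")),
    vcf)
  cohort <- readSSM(vcf, "vcf", sampleID = "s1")
  rec <- mutationRecords(cohort)
  expect_identical(nrow(rec), 1L)     # the indel is filtered out
  expect_identical(rec$sample_id, "s1")
  expect_identical(rec$chrom, "1")
  expect_identical(rec$pos, 100L)
  expect_identical(rec$ref, "C")
  expect_identical(rec$alt, "T")
})

test_that("annotation round-trips and is validated", {
  st <- smallStudy()
  ann <- readAnnotation(st$ref$annotation)
  expect_setequal(ann$genes$gene_id, unique(st$ref$annotation$gene_id))
  expect_identical(length(ann$transcripts),
                   nrow(st$ref$annotation))

  bad <- st$ref$annotation[1, ]
  bad$start <- bad$end + 5L
  expect_error(readAnnotation(bad), "start > end")

  dup <- st$ref$annotation[1:2, ]
  dup$gene_id <- "gX"
  dup$transcript_id <- c("t1", "t2")
  dup$gene_start <- c(1L, 5000L); dup$gene_end <- c(400L, 5400L)
  dup$start <- dup$gene_start; dup$end <- dup$gene_end
  expect_error(readAnnotation(dup), "gX")

  out <- st$ref$annotation[1, ]
  out$start <- out$gene_end + 1L; out$end <- out$gene_end + 10L
  expect_error(readAnnotation(out),
               paste0("outside gene '", out$gene_id, "'"))
})

test_that("gene assignment by overlap fills VCF-style records", {
  st <- smallStudy()
  ann <- readAnnotation(st$ref$annotation)
  g1 <- st$ref$annotation[1, ]
  df <- data.frame(sample_id = "s1", chrom = g1$chrom,
                   pos = as.integer((g1$gene_start + g1$gene_end) / 2),
                   ref = "C", alt = "T")
  cohort <- makeMutationCohort(df)
  cohort <- assignGenes(cohort, ann)
  expect_identical(mutationRecords(cohort)$gene_id, g1$gene_id)
  ## intergenic position stays unassigned
  df2 <- data.frame(sample_id = "s1", chrom = g1$chrom, pos = 1L,
                    ref = "C", alt = "T")
  c2 <- assignGenes(makeMutationCohort(df2), ann)
  expect_identical(mutationRecords(c2)$gene_id, "")
})

test_that("clinical survival eligibility follows the exclusion rule", {
  df <- data.frame(
    sample_id = paste0("d", 1:5),
    sex = c("male", "F", "female", "male", "male"),
    project_code = "PACA-AU",
    survival_time = c("365", "0", "NA", "100", "200"),
    vital_status = c("deceased", "alive", "alive", "unknown", "alive"),
    stage = "II", grade = "G2")
  cl <- readClinical(df)
  expect_identical(cl$survival_eligible, c(TRUE, FALSE, FALSE, FALSE,
                                           TRUE))
  expect_identical(cl$sex, c("male", "unknown", "female", "male",
                             "male"))
  expect_identical(cl$vital_status[4], "missing")
})

test_that("signature catalogs are reordered and renormalised", {
  labs <- motifClassLabels()
  set.seed(1)
  m <- matrix(runif(96 * 2), 96, 2)
  m <- sweep(m, 2, colSums(m) / 0.999, "/")   # columns sum to 0.999
  shuffle <- sample.int(96)
  df <- data.frame(motif = labs[shuffle], SBS1 = m[shuffle, 1],
                   SBS5 = m[shuffle, 2])
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat1 <- readSignatureCatalog(path)
  expect_identical(rownames(cat1), labs)
  expect_equal(colSums(cat1), c(SBS1 = 1, SBS5 = 1))
  expect_equal(unname(cat1[, 1]), m[, 1] / sum(m[, 1]))

  ## COSMIC notation is auto-detected
  df2 <- df
  df2$motif <- nativeToCosmic(df2$motif)
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat2 <- readSignatureCatalog(path)
  expect_equal(cat2, cat1)

  ## 95-row file is rejected
  write.table(df[-1, ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readSignatureCatalog(path), "96 rows")
})

test_that("files written by the generator read back losslessly", {
  dir <- tempfile()
  st <- smallStudy()
  out <- simulateStudy(st$cfg, dir)
  cohort <- readSSM(out$paths$ssm, "icgc_tsv")
  expect_identical(nrow(mutationRecords(cohort)),
                   nrow(unique(out$truth$mutations[,
                     c("sample_id", "chrom", "pos", "ref", "alt")])))
  expect_lte(nrow(mutationRecords(cohort)), nrow(out$ssm))
  ann <- readAnnotation(out$paths$annotation)
  expect_setequal(ann$genes$gene_id, unique(out$annotation$gene_id))
  cl <- readClinical(out$paths$clinical)
  expect_identical(nrow(cl), st$cfg@nSamples)
  ref <- Biostrings::readDNAStringSet(out$paths$reference)
  expect_identical(as.character(ref[[1]]),
                   unname(out$reference[1]))
})
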