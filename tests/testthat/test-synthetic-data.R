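test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(nSubtypes = 1L), "2 subtypes")
  expect_error(simulationConfig(subtypeProportions = c(0.5, 0.4, 0.2)),
               "probability vector")
  bad <- plantedSignatureSet(3)$signatures
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(simulationConfig(plantedSignatures = bad),
               "probability vectors")
  expect_error(simulationConfig(driverBoost = -1), "positive")
  expect_error(simulationConfig(mutationsPerSampleMean = 0), "positive")
  ## driver features must name existing genes
  cfg <- smallConfig()
  cfg@driverFeatures[[1]]$gene <- "NOPE"
  ref <- generateReference(cfg)
  expect_error(simulateCohort(cfg, ref$reference, ref$annotation),
               "NOPE")
})

test_that("generated annotation respects the configured layout", {
  cfg <- smallConfig()
  st <- smallStudy()
  ann <- st$ref$annotation
  genes <- unique(ann[, c("gene_id", "chrom", "gene_start",
                          "gene_end")])
  expect_identical(nrow(genes), cfg@nGenes)
  ## gene intervals on a chromosome do not overlap
  for (cc in unique(genes$chrom)) {
    g <- genes[genes$chrom == cc, ]
    g <- g[order(g$gene_start), ]
    expect_true(all(diff(g$gene_start) > 0))
    expect_true(all(utils::head(g$gene_end, -1) <
                      utils::tail(g$gene_start, -1)))
  }
  ## transcripts per gene within the configured range, inside the gene
  perGene <- table(ann$gene_id)
  expect_true(all(perGene >= cfg@transcriptsPerGene[1] &
                    perGene <= cfg@transcriptsPerGene[2]))
  expect_true(all(ann$start >= ann$gene_start &
                    ann$end <= ann$gene_end))
  ## oversized layouts raise a sizing error
  expect_error(generateReference(
    simulationConfig(nGenes = 10L, geneLengthBp = 1000L,
                     maxChromosomeBp = 2000L, nChromosomes = 1L)),
    "capacity")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- smallConfig(seed = 42L)
  a <- generateReference(cfg)
  b <- generateReference(cfg)
  expect_identical(a, b)
  ca <- simulateCohort(cfg, a$reference, a$annotation)
  cb <- simulateCohort(cfg, b$reference, b$annotation)
  expect_identical(ca, cb)
  ## and written files are byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  simulateStudy(cfg, d1); simulateStudy(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ## a different seed changes the data
  c2 <- simulateCohort(smallConfig(seed = 43L), a$reference,
                       a$annotation)
  expect_false(identical(ca$ssm, c2$ssm))
})

test_that("planted motif classes survive re-extraction from the FASTA", {
  st <- smallStudy()
  m <- st$coh$truth$mutations
  ctx <- extractContext(st$ref$reference, m$chrom, m$pos)
  expect_true(all(ctx$usable))
  lab <- canonicalizeMotif(m$ref, m$alt, ctx$left, ctx$right)
  expect_identical(lab, m$class)
})

test_that("cohort class frequencies converge to a planted signature", {
  ## all exposure on one planted signature; >= 1e4 mutations
  ps <- plantedSignatureSet(3)
  cfg <- simulationConfig(
    nSamples = 40L, nGenes = 60L, nChromosomes = 2L,
    mutationsPerSampleMean = 400,
    subtypeExposures = matrix(rep(c(1, 0, 0), each = 3), 3, 3),
    driverFeatures = list(data.frame(gene = character(0),
                                     motif = character(0)),
                          data.frame(gene = character(0),
                                     motif = character(0)),
                          data.frame(gene = character(0),
                                     motif = character(0))),
    seed = 99L)
  ref <- generateReference(cfg)
  coh <- simulateCohort(cfg, ref$reference, ref$annotation)
  m <- coh$truth$mutations
  expect_gt(nrow(m), 1e4)
  freq <- table(factor(m$class, levels = motifClassLabels()))
  freq <- freq / sum(freq)
  tv <- 0.5 * sum(abs(as.numeric(freq) - ps$signatures[, 1]))
  expect_lt(tv, 0.05)
})

test_that("censoring behaves at the degenerate and default settings", {
  st <- smallStudy()
  cl <- st$coh$clinical
  expect_true(any(cl$donor_vital_status == "alive"))   # some censoring
  cfg0 <- smallConfig(seed = 8L, censorRate = 0)
  ref <- generateReference(cfg0)
  coh0 <- simulateCohort(cfg0, ref$reference, ref$annotation)
  expect_true(all(coh0$clinical$donor_vital_status == "deceased"))
})

test_that("driver gene-motifs occur preferentially in their subtype", {
  st <- smallStudy()
  ch <- smallChain()
  occ <- occurrence(ch$gm)
  truth <- truthLabels(st$coh)
  ## pooled one-sided evidence across all planted driver features
  for (s in seq_along(st$cfg@driverFeatures)) {
    d <- st$cfg@driverFeatures[[s]]
    feats <- intersect(paste0(d$gene, "-", d$motif), rownames(occ))
    expect_gt(length(feats), 0)
    inS <- names(truth)[truth == paste0("S", s)]
    outS <- setdiff(colnames(occ), inS)
    a <- sum(occ[feats, inS]); b <- length(feats) * length(inS) - a
    c_ <- sum(occ[feats, outS])
    d_ <- length(feats) * length(outS) - c_
    p <- stats::phyper(a - 1, a + b, c_ + d_, a + c_,
                       lower.tail = FALSE)
    expect_lt(p, 0.01)
    ## and the raw occurrence frequency is strictly higher in-subtype
    expect_gt(mean(occ[feats, inS]), mean(occ[feats, outS]))
  }
})

test_that("SSM rows replicate the one-row-per-transcript dialect", {
  st <- smallStudy()
  ssm <- st$coh$ssm
  key <- paste(ssm$icgc_donor_id, ssm$chromosome,
               ssm$chromosome_start, ssm$mutated_to_allele)
  expect_gt(nrow(ssm), length(unique(key)))   # duplicated loci exist
  ## intergenic mutations carry no gene or transcript
  inter <- ssm$consequence_type == "intergenic_region"
  expect_true(any(inter))
  expect_true(all(ssm$gene_affected[inter] == ""))
  ## genic rows name a transcript of the right gene
  tx <- ssm$transcript_affected
  genic <- tx != ""
  expect_true(all(startsWith(tx[genic], ssm$gene_affected[genic])))
})

test_that("direct catalog simulation matches planted mixtures", {
  ps <- plantedSignatureSet(3)
  M <- simulateCatalogMatrix(ps$signatures, c(1, 0, 0), rep(5000, 30),
                             seed = 3)
  expect_identical(dim(M), c(96L, 30L))
  expect_identical(colSums(M), setNames(rep(5000, 30), colnames(M)))
  freq <- rowSums(M) / sum(M)
  expect_lt(0.5 * sum(abs(freq - ps$signatures[, 1])), 0.05)
  ## deterministic under seed
  expect_identical(M, simulateCatalogMatrix(ps$signatures, c(1, 0, 0),
                                            rep(5000, 30), seed = 3))
})
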