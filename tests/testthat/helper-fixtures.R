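## Shared fixtures, built once per test run and cached.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- builder()
  .fixtureEnv[[name]]
}

## a small but structured cohort: 3 subtypes, planted drivers
smallConfig <- function(seed = 5L, ...) {
  simulationConfig(nSamples = 60L, nGenes = 60L, nChromosomes = 2L,
                   geneLengthBp = 400L, driverGeneLengthBp = 650L,
                   mutationsPerSampleMean = 100, seed = seed, ...)
}

smallStudy <- function() fixture("smallStudy", function() {
  cfg <- smallConfig()
  ref <- generateReference(cfg)
  coh <- simulateCohort(cfg, ref$reference, ref$annotation)
  list(cfg = cfg, ref = ref, coh = coh)
})

ssmToCohort <- function(ssm) {
  makeMutationCohort(data.frame(
    sample_id = ssm$icgc_donor_id, chrom = ssm$chromosome,
    pos = ssm$chromosome_start, ref = ssm$reference_genome_allele,
    alt = ssm$mutated_to_allele, gene_id = ssm$gene_affected,
    transcript_id = ssm$transcript_affected,
    consequence = ssm$consequence_type,
    stringsAsFactors = FALSE))
}

smallChain <- function() fixture("smallChain", function() {
  st <- smallStudy()
  cohort <- ssmToCohort(st$coh$ssm)
  gm <- buildGeneMotifMatrix(cohort, st$ref$reference)
  catalog <- buildCatalogMatrix(cohort, st$ref$reference)
  list(cohort = cohort, gm = gm, catalog = catalog)
})

smallSelection <- function() fixture("smallSelection", function() {
  st <- smallStudy(); ch <- smallChain()
  universe <- sort(unique(st$ref$annotation$gene_id))
  ## the small fixture has 60 genes, so the top-tail gene rule needs
  ## alpha = 0.05 to admit its 3 driver genes (0.01 would select none)
  selectFeatures(ch$gm, genePresenceCounts(ch$cohort, universe),
                 alpha = 0.05)
})

driverLabels <- function(cfg) {
  unlist(lapply(cfg@driverFeatures, function(d)
    paste0(d$gene, "-", d$motif)))
}

truthLabels <- function(coh) {
  stats::setNames(paste0("S", coh$truth$subtype), coh$truth$sample_id)
}

## independent hypergeometric 2x2 oracle built on log-factorials
bruteFisher <- function(a, b, c, d) {
  lf <- function(n) lgamma(n + 1)
  m <- a + b; n2 <- c + d; K <- a + c; N <- m + n2
  ptab <- function(x) exp(lf(m) - lf(x) - lf(m - x) +
                            lf(n2) - lf(K - x) - lf(n2 - K + x) -
                            (lf(N) - lf(K) - lf(N - K)))
  xs <- max(0, K - n2):min(K, m)
  ps <- vapply(xs, ptab, 0)
  pobs <- ptab(a)
  sum(ps[ps <= pobs * (1 + 1e-7)])
}
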