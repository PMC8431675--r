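test_that("rate tables match worked fractions and edge values", {
  pres <- matrix(0L, 100, 3,
                 dimnames = list(sprintf("s%03d", 1:100),
                                 c("PTPRD", "ALLHIT", "NONE")))
  labels <- setNames(rep(c("PCS1", "PCS2"), c(70, 30)),
                     rownames(pres))
  pres[1:57, "PTPRD"] <- 1L        # 57 of the 70 PCS1 samples
  pres[, "ALLHIT"] <- 1L
  rt <- rateTable(labels, pres)
  expect_equal(unname(rt$rates["PCS1", "PTPRD"]), 57 / 70)
  expect_equal(round(100 * rt$rates["PCS1", "PTPRD"], 1), 81.4)
  expect_equal(unname(rt$rates[, "ALLHIT"]), c(1, 1))
  expect_equal(unname(rt$rates[, "NONE"]), c(0, 0))
  expect_identical(unname(rt$sizes), c(70L, 30L))
  ## sample order does not matter
  perm <- sample(nrow(pres))
  rt2 <- rateTable(labels[perm], pres[perm, ])
  expect_equal(rt2$rates, rt$rates)
  expect_error(rateTable(labels[0], pres), "share no samples")
})

test_that("differential rates are antisymmetric and signed", {
  rt <- list(rates = rbind(A = c(g = 0.8, h = 0.1),
                           B = c(g = 0.3, h = 0.1),
                           C = c(g = 0.5, h = 0.9)),
             sizes = c(A = 10L, B = 10L, C = 10L))
  d <- differentialRates(rt)
  pick <- function(a, b, item)
    d$diff[d$subtype_a == a & d$subtype_b == b & d$item == item]
  expect_equal(pick("A", "B", "g"), 0.5)
  expect_equal(pick("B", "A", "g"), -0.5)
  for (i in seq_len(nrow(d)))
    expect_equal(d$diff[i],
                 -pick(d$subtype_b[i], d$subtype_a[i], d$item[i]))
  same <- differentialRates(list(rates = rbind(A = c(g = 0.4),
                                               B = c(g = 0.4))))
  expect_true(all(same$diff == 0))
})

test_that("Welch t-test matches stats::t.test and handles degeneracy", {
  a <- c(0.1, 0.4, 0.25, 0.9, 0.33, 0.7)
  b <- c(0.5, 0.6, 0.55, 0.8, 0.2, 0.4)
  mine <- rateTTest(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p, ref$p.value)
  ## symmetry
  swap <- rateTTest(b, a)
  expect_equal(swap$t, -mine$t)
  expect_equal(swap$p, mine$p)
  ## identical vectors
  same <- rateTTest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ## constant but different -> degenerate flag
  deg <- rateTTest(rep(0, 4), rep(1, 4))
  expect_true(deg$degenerate)
  ## near-constant separated vectors are overwhelmingly significant
  jit <- rateTTest(rep(0, 4), 1 + c(1e-9, -1e-9, 2e-9, 0))
  expect_lt(jit$p, 1e-6)
  expect_equal(rateTTest(rep(0.5, 4), rep(0.5, 4))$p, 1)
})

test_that("Fisher p-values match the hand example and fisher.test", {
  expect_equal(fisherExact2x2(1, 9, 1, 9), 1)
  ## 2 / choose(20, 10), the two extreme tables
  expect_equal(fisherExact2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_equal(fisherExact2x2(10, 0, 0, 10), 1.0825e-5,
               tolerance = 1e-4)
  expect_equal(fisherExact2x2(0, 0, 0, 0), 1)
  set.seed(31)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), 2, 2)
    expect_equal(fisherExact2x2(tab[1, 1], tab[1, 2],
                                tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisherExact2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher agrees with the log-factorial enumeration oracle", {
  ## random sweep here; the exhaustive total <= 30 sweep runs in the
  ## acceptance suite
  set.seed(17)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(5:30, 1), rep(0.25, 4)))
    expect_equal(
      fisherExact2x2(cells[1], cells[2], cells[3], cells[4]),
      bruteFisher(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-12)
  }
})

test_that("permutation thresholds use the prescribed tail rank", {
  expect_error(permutationThresholds(matrix(1, 1, 2), 5, nPerm = 100,
                                     tailFrac = 0.001), "at least 1")
  ## rank arithmetic: ceiling(tailFrac * nPerm)
  set.seed(2)
  counts <- matrix(rbinom(2 * 20, 10, 0.3), 2, 20)
  r <- permutationThresholds(counts, c(10L, 10L), nPerm = 200,
                             tailFrac = 0.01, seed = 3)
  expect_identical(r$rank, 2L)
  r2 <- permutationThresholds(counts, c(10L, 10L), nPerm = 2000,
                              tailFrac = 5e-4, seed = 3)
  expect_identical(r2$rank, 1L)
  ## the reference-scale arithmetic: 10,000 x 0.0005 -> rank 5
  expect_identical(as.integer(ceiling(0.0005 * 10000)), 5L)
})

test_that("count permutation preserves per-subtype totals", {
  set.seed(8)
  counts <- matrix(rbinom(3 * 30, 40, 0.4), 3, 30)
  r <- permutationThresholds(counts, c(40L, 40L, 40L), nPerm = 20,
                             tailFrac = 0.05,
                             scheme = "count_permutation", seed = 1)
  expect_true(all(dim(r$thresholds) == c(3, 30)))
  ## the capped multinomial scheme also preserves totals and caps
  for (i in 1:20) {
    draw <- MotifSubtypes:::.multinomialCapped(500, 30, 20)
    expect_identical(sum(draw), 500L)
    expect_true(all(draw <= 20L))
  }
})

test_that("null-cohort association is calibrated (no false calls)", {
  ## exact null: identical exposures, no drivers
  cfg <- nullSimulationConfig(nSamples = 60L, nGenes = 60L,
                              nChromosomes = 2L, geneLengthBp = 400L,
                              mutationsPerSampleMean = 100,
                              seed = 77L)
  ref <- generateReference(cfg)
  coh <- simulateCohort(cfg, ref$reference, ref$annotation)
  cohort <- ssmToCohort(coh$ssm)
  truth <- truthLabels(coh)
  gp <- genePresenceMatrix(cohort,
                           sort(unique(ref$annotation$gene_id)))
  rt <- rateTable(truth, gp)
  counts <- round(rt$rates * rt$sizes[rownames(rt$rates)])
  perm <- permutationThresholds(counts, rt$sizes, nPerm = 400,
                                tailFrac = 0.0025, seed = 5)
  rate <- mean(perm$observedP < perm$thresholds)
  expect_lte(rate, 10 * 0.0025)
})

test_that("association calls require both the p and rate gates", {
  rates <- rbind(A = c(g1 = 0.6, g2 = 0.4, g3 = 0.5),
                 B = c(g1 = 0.1, g2 = 0.1, g3 = 0.9))
  p <- rbind(A = c(1e-9, 1e-9, 0.5), B = c(0.9, 0.9, 1e-9))
  thr <- rbind(A = rep(1e-4, 3), B = rep(1e-4, 3))
  colnames(p) <- colnames(thr) <- colnames(rates)
  a <- associateGenes(rates, p, thr)
  get <- function(s, g) a$associated[a$subtype == s & a$gene == g]
  expect_true(get("A", "g1"))        # both gates pass
  expect_false(get("A", "g2"))       # rate 0.4 < 0.5
  expect_false(get("A", "g3"))       # p above threshold
  expect_true(get("B", "g3"))
  ## rate exactly 0.5 is inclusive
  rates["A", "g2"] <- 0.5
  a2 <- associateGenes(rates, p, thr)
  expect_true(a2$associated[a2$subtype == "A" & a2$gene == "g2"])
})

test_that("motif preference testing restricts to the two subtypes", {
  ch <- smallChain()
  sel <- smallSelection()
  labels <- truthLabels(smallStudy()$coh)
  feat <- candidateFeatures(sel)[1]
  r <- motifPreferenceTest(ch$gm, feat, labels, "S1", "S2")
  expect_true(r$p >= 0 && r$p <= 1)
  expect_identical(sum(r$table), sum(labels %in% c("S1", "S2")))
  ## symmetric in subtype order
  r2 <- motifPreferenceTest(ch$gm, feat, labels, "S2", "S1")
  expect_equal(r$p, r2$p)
  ## extreme contingency reproduces the enumeration value
  occ <- matrix(0L, 1, 20,
                dimnames = list("g-CT-A.G", sprintf("x%02d", 1:20)))
  occ[1, 1:10] <- 1L
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(counts = occ, occurrence = occ),
    rowData = S4Vectors::DataFrame(gene = "g", motif = "CT-A.G"))
  gm <- new("GeneMotifExperiment", se)
  lab2 <- setNames(rep(c("A", "B"), each = 10), colnames(occ))
  rx <- motifPreferenceTest(gm, "g-CT-A.G", lab2, "A", "B")
  expect_equal(rx$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_error(motifPreferenceTest(gm, "nope", lab2, "A", "B"),
               "nope")
})

test_that("transcript rates are contained by their gene rates", {
  ch <- smallChain()
  labels <- truthLabels(smallStudy()$coh)
  tx <- transcriptRates(ch$cohort, labels)
  expect_true(all(tx$rates >= 0 & tx$rates <= 1))
  gp <- genePresenceMatrix(ch$cohort)
  gr <- rateTable(labels, gp)
  ## per-gene containment: a transcript cannot be hit in more samples
  ## than its gene
  hits <- unique(transcriptHits(ch$cohort)[, c("gene_id",
                                               "transcript_id")])
  for (i in sample(nrow(hits), 25)) {
    g <- hits$gene_id[i]; t <- hits$transcript_id[i]
    expect_true(all(tx$rates[, t] <= gr$rates[, g] + 1e-12))
  }
  ## a never-annotated transcript is absent; an unmutated one is 0
  expect_false("GHOST.T1" %in% colnames(tx$rates))
})

test_that("driver genes are associated to their subtype under strong selection", {
  ## sparse genome, boost 200: the regime where within-subtype driver
  ## rates approach 1 against a ~20 percent background
  cfg <- associationSimulationConfig(seed = 13L)
  ref <- generateReference(cfg)
  coh <- simulateCohort(cfg, ref$reference, ref$annotation)
  cohort <- ssmToCohort(coh$ssm)
  truth <- truthLabels(coh)
  gp <- genePresenceMatrix(cohort,
                           sort(unique(ref$annotation$gene_id)))
  rt <- rateTable(truth, gp)
  counts <- round(rt$rates * rt$sizes[rownames(rt$rates)])
  perm <- permutationThresholds(counts, rt$sizes, nPerm = 500L,
                                tailFrac = 0.002, seed = 5L)
  assoc <- associateGenes(rt$rates, perm$observedP, perm$thresholds)
  driverGenes <- unique(unlist(lapply(cfg@driverFeatures,
                                      `[[`, "gene")))
  for (s in seq_along(cfg@driverFeatures)) {
    g <- unique(cfg@driverFeatures[[s]]$gene)
    hit <- assoc$associated[assoc$subtype == paste0("S", s) &
                              assoc$gene == g]
    expect_true(all(hit))
  }
  ## drivers are called only for their own subtype, and nothing else is
  offTarget <- assoc$associated &
    !(paste0("GENE000", match(assoc$subtype,
                              paste0("S", 1:3))) == assoc$gene)
  expect_identical(sum(offTarget), 0L)
})
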