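#' @importFrom utils packageVersion
NULL

.hashString <- function(x) {
  v <- utf8ToInt(x)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- (h * 33 + sum(chunk * (seq_along(chunk) %% 97 + 1))) %%
      2147483647
  }
  sprintf("%08x", as.integer(h))
}

.writeTSV <- function(x, path, rowLabel = NULL) {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- rowLabel %||% "id"
    x <- df
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Per-sample gene presence matrix
#'
#' Binary samples x genes matrix: 1 when the sample has at least one
#' deduplicated SNV in the gene.
#'
#' @param cohort A \linkS4class{MutationCohort}.
#' @param universe Optional gene universe (columns).
#' @return Binary integer matrix.
#' @export
genePresenceMatrix <- function(cohort, universe = NULL) {
  rec <- cohort@records
  rec <- unique(rec[rec$gene_id != "", c("sample_id", "gene_id")])
  if (is.null(universe)) universe <- sort(unique(rec$gene_id))
  samples <- cohort@samples
  m <- matrix(0L, length(samples), length(universe),
              dimnames = list(samples, universe))
  rec <- rec[rec$gene_id %in% universe, , drop = FALSE]
  m[cbind(match(rec$sample_id, samples),
          match(rec$gene_id, universe))] <- 1L
  m
}

#' Run the full subtype-discovery pipeline
#'
#' Executes reading/cleaning, gene-motif matrix construction, feature
#' selection, recursive clustering, subtype statistics (rates,
#' differential rates, permutation-calibrated gene association,
#' transcript rates), signature deciphering and survival analysis,
#' writing every result table plus a manifest to \code{outDir}.
#'
#' @param config Either a YAML path or a list with elements
#'   \code{paths} (ssm, reference, annotation, clinical, optional
#'   signature_catalog), \code{alpha}, \code{min_frac},
#'   \code{min_abs}, \code{k_range}, \code{permutation} (n_perm,
#'   tail_frac, scheme), \code{signatures} (k_range, n_boot,
#'   by_subtype), \code{seed}, \code{out_dir}.
#' @param skip Character vector of stages to skip (among
#'   \code{"signatures"}, \code{"survival"}, \code{"association"}).
#' @return Invisibly, a list of in-memory stage results plus the
#'   manifest.
#' @export
runAll <- function(config, skip = character(0)) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- config
  seed <- as.integer(cfg$seed %||% 1L)
  outDir <- cfg$out_dir %||% stop("config needs out_dir")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  files <- character(0)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  ## stage: io ---------------------------------------------------------
  io <- clock("io", {
    cohort <- readSSM(cfg$paths$ssm, format = cfg$format %||% "icgc_tsv")
    annotation <- readAnnotation(cfg$paths$annotation)
    cohort <- assignGenes(cohort, annotation)
    clinical <- readClinical(cfg$paths$clinical)
    reference <- referenceAsStrings(cfg$paths$reference)
    list(cohort = cohort, annotation = annotation,
         clinical = clinical, reference = reference)
  })

  ## stage: matrices ---------------------------------------------------
  mats <- clock("matrices", {
    gm <- buildGeneMotifMatrix(io$cohort, io$reference)
    catalog <- buildCatalogMatrix(io$cohort, io$reference)
    list(gm = gm, catalog = catalog)
  })
  files <- c(files,
    .writeTSV(motifCounts(mats$gm), file.path(outDir,
      "gene_motif_counts.tsv"), "feature"),
    .writeTSV(motifCounts(mats$catalog), file.path(outDir,
      "catalog_96.tsv"), "motif"))

  ## stage: selection --------------------------------------------------
  geneUniverse <- sort(unique(io$annotation$genes$gene_id))
  sel <- clock("selection", {
    selectFeatures(mats$gm,
                   genePresenceCounts(io$cohort, geneUniverse),
                   alpha = cfg$alpha %||% 0.01)
  })
  selPath <- file.path(outDir, "selection.json")
  jsonlite::write_json(list(
    gene_threshold = sel@geneThreshold,
    motif_threshold = sel@motifThreshold,
    significant_genes = sel@significantGenes,
    candidate_features = sel@candidateFeatures,
    alpha = sel@alpha, denominators = as.list(sel@denominators)),
    selPath, auto_unbox = TRUE, digits = NA)
  files <- c(files, selPath,
             .writeTSV(data.frame(feature = sel@candidateFeatures),
                       file.path(outDir, "candidate_features.tsv")))

  ## stage: clustering -------------------------------------------------
  tree <- clock("clustering", {
    X <- t(occurrence(mats$gm)[sel@candidateFeatures, , drop = FALSE])
    recursiveCluster(X, minFrac = cfg$min_frac %||% 0.01,
                     minAbs = cfg$min_abs %||% 7L,
                     kRange = seq_len(cfg$k_max %||% 9L),
                     seed = deriveSeed(seed, "clustering"))
  })
  labels <- subtypeLabels(tree)
  files <- c(files, .writeTSV(
    data.frame(sample_id = names(labels), subtype = unname(labels)),
    file.path(outDir, "labels.tsv")))
  pca <- pcaProject(t(occurrence(mats$gm)[sel@candidateFeatures, ,
                                          drop = FALSE]))
  files <- c(files, .writeTSV(cbind(
    data.frame(sample_id = rownames(pca$coordinates)),
    as.data.frame(pca$coordinates)),
    file.path(outDir, "pca_coordinates.tsv")))

  core <- labels[labels != "OUTLIER"]
  results <- list(cohort = io$cohort, selection = sel, tree = tree,
                  geneMotifs = mats$gm, catalog = mats$catalog,
                  pca = pca)

  ## stage: stats ------------------------------------------------------
  if (length(unique(core)) >= 2L) {
    stats <- clock("stats", {
      gp <- genePresenceMatrix(io$cohort, geneUniverse)
      rt <- rateTable(core, gp)
      diffs <- differentialRates(rt)
      counts <- round(rt$rates * rt$sizes[rownames(rt$rates)])
      assoc <- NULL
      if (!("association" %in% skip)) {
        perm <- permutationThresholds(
          counts, rt$sizes,
          nPerm = cfg$permutation$n_perm %||% 2000L,
          tailFrac = cfg$permutation$tail_frac %||% 5e-4,
          scheme = cfg$permutation$scheme %||% "multinomial_uniform",
          seed = deriveSeed(seed, "association"))
        assoc <- associateGenes(rt$rates, perm$observedP,
                                perm$thresholds)
      }
      tx <- transcriptRates(io$cohort, core)
      list(rates = rt, diffs = diffs, association = assoc,
           transcript = tx)
    })
    files <- c(files,
      .writeTSV(stats$rates$rates, file.path(outDir, "gene_rates.tsv"),
                "subtype"),
      .writeTSV(stats$diffs, file.path(outDir, "differential_rates.tsv")),
      .writeTSV(stats$transcript$rates,
                file.path(outDir, "transcript_rates.tsv"), "subtype"))
    if (!is.null(stats$association))
      files <- c(files, .writeTSV(stats$association,
        file.path(outDir, "gene_association.tsv")))
    results$stats <- stats
  }

  ## stage: signatures -------------------------------------------------
  if (!("signatures" %in% skip)) {
    sig <- clock("signatures", {
      sweep <- sweepSignatureK(
        mats$catalog,
        kRange = seq(cfg$signatures$k_min %||% 1L,
                     cfg$signatures$k_max %||% 4L),
        nBoot = cfg$signatures$n_boot %||% 20L,
        seed = deriveSeed(seed, "signatures"))
      best <- sweep$fits[[match(sweep$suggestion, sweep$table$k)]]
      cmp <- NULL
      if (!is.null(cfg$paths$signature_catalog)) {
        ref <- readSignatureCatalog(cfg$paths$signature_catalog)
        cmp <- compareToReference(best, ref)
      }
      list(sweep = sweep, best = best, comparison = cmp)
    })
    files <- c(files,
      .writeTSV(signatures(sig$best),
                file.path(outDir, "signatures.tsv"), "motif"),
      .writeTSV(exposures(sig$best),
                file.path(outDir, "exposures.tsv"), "signature"),
      .writeTSV(sig$sweep$table,
                file.path(outDir, "signature_diagnostics.tsv")))
    if (!is.null(sig$comparison))
      files <- c(files, .writeTSV(sig$comparison$matches,
        file.path(outDir, "signature_matches.tsv")))
    results$signatures <- sig
  }

  ## stage: survival ---------------------------------------------------
  if (!("survival" %in% skip) && length(unique(core)) >= 2L) {
    surv <- clock("survival", {
      si <- survivalInput(labels, io$clinical)
      curves <- lapply(split(si, si$group), function(d)
        kmEstimate(d$time, d$event))
      tests <- pairwiseSurvivalTests(si$time, si$event, si$group)
      freq <- clinicalFrequencies(core, io$clinical)
      list(input = si, curves = curves, tests = tests,
           frequencies = freq)
    })
    summaryDf <- do.call(rbind, lapply(names(surv$curves), function(g) {
      cv <- surv$curves[[g]]
      data.frame(subtype = g, n = cv@n, median_months = cv@median,
                 restricted_mean_months = cv@restrictedMean,
                 stringsAsFactors = FALSE)
    }))
    files <- c(files,
      .writeTSV(summaryDf, file.path(outDir, "survival_summary.tsv")),
      .writeTSV(surv$tests, file.path(outDir, "survival_tests.tsv")),
      .writeTSV(as.data.frame(surv$frequencies$project$counts),
                file.path(outDir, "project_frequencies.tsv")),
      .writeTSV(as.data.frame(surv$frequencies$sex$counts),
                file.path(outDir, "sex_frequencies.tsv")))
    results$survival <- surv
  }

  ## manifest ----------------------------------------------------------
  manifest <- list(
    package = "MotifSubtypes",
    version = as.character(packageVersion("MotifSubtypes")),
    seed = seed,
    config_hash = .hashString(jsonlite::toJSON(
      cfg[setdiff(names(cfg), "out_dir")], auto_unbox = TRUE)),
    files = basename(files),
    timings_sec = timings)
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}
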