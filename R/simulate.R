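#' @importFrom stats rpois rexp runif rmultinom
NULL

#' Derive a stage-specific RNG seed from a global seed
#'
#' A single pipeline seed is fanned out to independent stage seeds so
#' that skipping or re-running one stage leaves the others unchanged.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return Integer seed in [0, 2^31).
#' @export
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

## ---------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------

#' Configuration of the synthetic cohort generator
#'
#' See \code{\link{simulationConfig}} for field semantics and defaults.
#'
#' @export
setClass("SimulationConfig", slots = c(
  nSamples = "integer", nChromosomes = "integer", nGenes = "integer",
  geneLengthBp = "integer", driverGeneLengthBp = "integer",
  intergenicBp = "integer", maxChromosomeBp = "integer",
  transcriptsPerGene = "integer",
  nSubtypes = "integer", subtypeProportions = "numeric",
  plantedSignatures = "matrix", subtypeExposures = "matrix",
  mutationsPerSampleMean = "numeric",
  driverFeatures = "list", driverBoost = "numeric",
  survivalHazards = "numeric", censorRate = "numeric",
  sexProbs = "matrix", projectProbs = "matrix",
  strand = "character", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  probOK <- function(p) abs(sum(p) - 1) <= 1e-9 && all(p >= 0)
  if (object@nSubtypes < 2L) return("at least 2 subtypes are required")
  if (!probOK(object@subtypeProportions) ||
      length(object@subtypeProportions) != object@nSubtypes)
    return("subtypeProportions must be a probability vector over subtypes")
  W <- object@plantedSignatures
  if (nrow(W) != 96L) return("plantedSignatures must have 96 rows")
  if (any(W < 0) || any(abs(colSums(W) - 1) > 1e-9))
    return("plantedSignatures columns must be probability vectors")
  E <- object@subtypeExposures
  if (nrow(E) != object@nSubtypes || ncol(E) != ncol(W))
    return("subtypeExposures must be nSubtypes x nPlanted")
  if (any(E < 0) || any(abs(rowSums(E) - 1) > 1e-9))
    return("subtypeExposures rows must be probability vectors")
  if (length(object@survivalHazards) != object@nSubtypes ||
      any(object@survivalHazards <= 0))
    return("survivalHazards must be positive, one per subtype")
  if (any(!vapply(seq_len(nrow(object@sexProbs)), function(i)
    probOK(object@sexProbs[i, ]), TRUE)))
    return("sexProbs rows must be probability vectors")
  if (any(!vapply(seq_len(nrow(object@projectProbs)), function(i)
    probOK(object@projectProbs[i, ]), TRUE)))
    return("projectProbs rows must be probability vectors")
  if (length(object@driverFeatures) &&
      length(object@driverFeatures) != object@nSubtypes)
    return("driverFeatures must have one entry per subtype (or be empty)")
  if (length(object@transcriptsPerGene) != 2L ||
      object@transcriptsPerGene[1] < 1L ||
      object@transcriptsPerGene[1] > object@transcriptsPerGene[2])
    return("transcriptsPerGene must be an increasing integer pair >= 1")
  if (object@mutationsPerSampleMean <= 0)
    return("mutationsPerSampleMean must be positive")
  if (object@driverBoost <= 0) return("driverBoost must be positive")
  if (object@censorRate < 0) return("censorRate must be nonnegative")
  TRUE
})

.syntheticGeneID <- function(i) sprintf("GENE%04d", i)

#' Default planted signatures and driver features
#'
#' Builds the study's planted truth: each subtype has its own
#' mutational signature placing mass \code{driverMass} uniformly on its
#' driver motif classes and the remainder uniformly on the classes
#' used by no subtype as a driver class. Driver classes are spaced
#' deterministically across the 96-class order; subtype \code{s} uses
#' gene \code{GENE000s} for all of its driver gene-motifs.
#'
#' @param nSubtypes Number of subtypes.
#' @param classesPerSubtype Integer vector of driver-class counts per
#'   subtype (defaults to 20 pairs total for 3 subtypes: 7, 7, 6).
#' @param driverMass Signature mass placed on the driver classes.
#' @return List with \code{signatures} (96 x nSubtypes),
#'   \code{driverFeatures} (per subtype data.frame of gene and motif).
#' @export
plantedSignatureSet <- function(nSubtypes = 3L,
                                classesPerSubtype = NULL,
                                driverMass = 0.8) {
  labels <- motifClassLabels()
  if (is.null(classesPerSubtype)) {
    total <- 20L
    base <- total %/% nSubtypes
    classesPerSubtype <- rep(base, nSubtypes)
    extra <- total - base * nSubtypes
    if (extra > 0) classesPerSubtype[seq_len(extra)] <-
        classesPerSubtype[seq_len(extra)] + 1L
  }
  ## spaced, disjoint driver classes
  need <- sum(classesPerSubtype)
  idx <- round(seq(1, 96, length.out = need))
  idx <- unique(as.integer(idx))
  stopifnot(length(idx) == need)
  split_idx <- split(idx, rep(seq_len(nSubtypes), classesPerSubtype))
  allDrivers <- idx
  W <- matrix(0, 96L, nSubtypes,
              dimnames = list(labels, paste0("PS", seq_len(nSubtypes))))
  drv <- vector("list", nSubtypes)
  for (s in seq_len(nSubtypes)) {
    own <- split_idx[[s]]
    W[own, s] <- driverMass / length(own)
    rest <- setdiff(seq_len(96L), allDrivers)
    W[rest, s] <- (1 - driverMass) / length(rest)
    drv[[s]] <- data.frame(
      gene = .syntheticGeneID(s),
      motif = labels[own],
      stringsAsFactors = FALSE)
  }
  list(signatures = W, driverFeatures = drv)
}

#' Build a synthetic-cohort configuration
#'
#' The defaults define the package's reference study conditions: 300
#' samples in 3 subtypes of a priori proportions (0.35, 0.35, 0.30),
#' a 3-chromosome uniform-random genome of 300 genes (driver genes
#' slightly longer, mirroring the large multi-exon loci that dominate
#' real driver lists), one planted signature per subtype, 20 driver
#' gene-motifs boosted 20-fold, exponential survival with per-subtype
#' hazards and exponential censoring.
#'
#' @param nSamples Cohort size.
#' @param nSubtypes Number of planted subtypes.
#' @param subtypeProportions Probability vector over subtypes.
#' @param nChromosomes,nGenes,geneLengthBp,driverGeneLengthBp,intergenicBp
#'   Genome layout (lengths in bp; 1-based inclusive gene intervals).
#' @param maxChromosomeBp Sizing guard; exceeding it is an error.
#' @param transcriptsPerGene Integer pair (min, max).
#' @param plantedSignatures 96 x k column-stochastic matrix (default:
#'   \code{\link{plantedSignatureSet}}).
#' @param subtypeExposures nSubtypes x k row-stochastic matrix.
#' @param mutationsPerSampleMean Poisson mean of per-sample SNV count.
#' @param driverFeatures Per-subtype data.frames with columns
#'   \code{gene}, \code{motif}; empty list for a null cohort.
#' @param driverBoost Multiplier on eligible positions of a subtype's
#'   driver (gene, motif) pairs.
#' @param survivalHazards Exponential hazards per subtype (1/month).
#' @param censorRate Exponential censoring rate (1/month); 0 disables
#'   censoring.
#' @param sexProbs nSubtypes x 2 matrix (male, female).
#' @param projectProbs nSubtypes x P matrix over project codes
#'   (columns named).
#' @param strand Gene strand, \code{"+"} (default) or \code{"-"}
#'   (exists to exercise reverse-complement handling downstream).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(
    nSamples = 300L,
    nSubtypes = 3L,
    subtypeProportions = NULL,
    nChromosomes = 3L,
    nGenes = 300L,
    geneLengthBp = 500L,
    driverGeneLengthBp = 650L,
    intergenicBp = 100L,
    maxChromosomeBp = 5000000L,
    transcriptsPerGene = c(1L, 3L),
    plantedSignatures = NULL,
    subtypeExposures = NULL,
    mutationsPerSampleMean = 600,
    driverFeatures = NULL,
    driverBoost = 20,
    survivalHazards = NULL,
    censorRate = 0.02,
    sexProbs = NULL,
    projectProbs = NULL,
    strand = "+",
    seed = 1L) {
  if (is.null(subtypeProportions))
    subtypeProportions <- if (nSubtypes == 3L) c(0.35, 0.35, 0.30) else
      rep(1 / nSubtypes, nSubtypes)
  planted <- NULL
  if (is.null(plantedSignatures) || is.null(driverFeatures)) {
    planted <- plantedSignatureSet(nSubtypes)
    if (is.null(plantedSignatures)) plantedSignatures <- planted$signatures
    if (is.null(driverFeatures)) driverFeatures <- planted$driverFeatures
  }
  k <- ncol(plantedSignatures)
  if (is.null(subtypeExposures)) {
    subtypeExposures <- matrix((1 - 0.9) / (k - 1), nSubtypes, k)
    for (s in seq_len(min(nSubtypes, k)))
      subtypeExposures[s, s] <- 0.9
  }
  if (is.null(survivalHazards))
    survivalHazards <- seq(0.025, 0.05,
                           length.out = nSubtypes)
  if (is.null(sexProbs)) {
    sexProbs <- matrix(rep(c(0.57, 0.43), each = nSubtypes),
                       nSubtypes, 2)
  }
  colnames(sexProbs) <- c("male", "female")
  if (is.null(projectProbs)) {
    base <- c(0.4, 0.3, 0.2, 0.1)
    projectProbs <- t(vapply(seq_len(nSubtypes), function(s) {
      p <- base[((seq_along(base) + s - 2L) %% length(base)) + 1L]
      p / sum(p)
    }, numeric(4)))
    colnames(projectProbs) <- c("PACA-AU", "PACA-CA", "PAEN-AU",
                                "PAEN-IT")
  }
  if (is.null(colnames(projectProbs)))
    colnames(projectProbs) <- paste0("PROJ", seq_len(ncol(projectProbs)))
  methods::new("SimulationConfig",
    nSamples = as.integer(nSamples),
    nChromosomes = as.integer(nChromosomes),
    nGenes = as.integer(nGenes),
    geneLengthBp = as.integer(geneLengthBp),
    driverGeneLengthBp = as.integer(driverGeneLengthBp),
    intergenicBp = as.integer(intergenicBp),
    maxChromosomeBp = as.integer(maxChromosomeBp),
    transcriptsPerGene = as.integer(transcriptsPerGene),
    nSubtypes = as.integer(nSubtypes),
    subtypeProportions = subtypeProportions,
    plantedSignatures = plantedSignatures,
    subtypeExposures = subtypeExposures,
    mutationsPerSampleMean = mutationsPerSampleMean,
    driverFeatures = if (is.null(driverFeatures)) list() else
      driverFeatures,
    driverBoost = driverBoost,
    survivalHazards = survivalHazards,
    censorRate = censorRate,
    sexProbs = sexProbs,
    projectProbs = projectProbs,
    strand = strand,
    seed = as.integer(seed))
}

#' Configuration of a null cohort (no planted structure)
#'
#' All subtypes share the same uniform signature mixture and there are
#' no driver features, so gene occurrence is exactly independent of
#' the subtype label. Used to calibrate association thresholds.
#'
#' @param ... Passed to \code{\link{simulationConfig}}.
#' @return A \linkS4class{SimulationConfig}.
#' @export
nullSimulationConfig <- function(...) {
  cfg <- simulationConfig(...)
  k <- ncol(cfg@plantedSignatures)
  cfg@subtypeExposures <- matrix(1 / k, cfg@nSubtypes, k)
  cfg@driverFeatures <- list()
  methods::validObject(cfg)
  cfg
}

#' Configuration of a sparse cohort for gene-association studies
#'
#' A variant of the default study conditions emulating the regime the
#' permutation-calibrated association test is designed for: genes
#' occupy a small fraction of the genome (wide intergenic spacers), so
#' a typical gene is mutated in only ~20 percent of samples, while
#' driver (gene, motif) pairs are under strong positive selection
#' (boost 200). Subtype-restricted driver genes then reach ~100
#' percent within-subtype mutation rates against a low background,
#' the contrast the Fisher/permutation machinery calls.
#'
#' @param ... Overrides passed to \code{\link{simulationConfig}}.
#' @return A \linkS4class{SimulationConfig}.
#' @export
associationSimulationConfig <- function(...) {
  simulationConfig(geneLengthBp = 500L, driverGeneLengthBp = 500L,
                   intergenicBp = 2800L, driverBoost = 200,
                   mutationsPerSampleMean = 450, ...)
}

## ---------------------------------------------------------------------
## Reference genome + annotation
## ---------------------------------------------------------------------

#' Generate the synthetic reference genome and annotation
#'
#' Genes are laid out left to right on \code{nChromosomes} chromosomes
#' (round-robin by index) with \code{intergenicBp} spacers; gene
#' \code{GENE000s} (the driver gene of subtype s) uses
#' \code{driverGeneLengthBp}. Sequences are uniform random A/C/G/T
#' from the seeded generator. Every gene gets 1..max transcripts, each
#' a random sub-interval of the gene.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return List with \code{reference} (named character vector of
#'   sequences), \code{annotation} (data.frame, one row per
#'   transcript, with gene interval columns).
#' @export
generateReference <- function(config) {
  methods::validObject(config)
  set.seed(deriveSeed(config@seed, "reference"))
  nDriver <- length(config@driverFeatures)
  driverGenes <- if (nDriver)
    unique(unlist(lapply(config@driverFeatures, `[[`, "gene"))) else
      character(0)
  geneIDs <- .syntheticGeneID(seq_len(config@nGenes))
  lens <- ifelse(geneIDs %in% driverGenes,
                 config@driverGeneLengthBp, config@geneLengthBp)
  chromOf <- ((seq_len(config@nGenes) - 1L) %% config@nChromosomes) + 1L
  ann <- NULL
  seqs <- character(config@nChromosomes)
  names(seqs) <- paste0("chrS", seq_len(config@nChromosomes))
  rows <- list()
  for (cc in seq_len(config@nChromosomes)) {
    gi <- which(chromOf == cc)
    needed <- sum(lens[gi]) +
      config@intergenicBp * (length(gi) + 1L)
    if (needed > config@maxChromosomeBp)
      stop("genes do not fit on chromosome ", cc,
           ": need ", needed, " bp, capacity ", config@maxChromosomeBp)
    pos <- config@intergenicBp + 1L
    starts <- integer(length(gi)); ends <- integer(length(gi))
    for (j in seq_along(gi)) {
      starts[j] <- pos
      ends[j] <- pos + lens[gi[j]] - 1L
      pos <- ends[j] + config@intergenicBp + 1L
    }
    L <- pos - 1L
    seqs[cc] <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    for (j in seq_along(gi)) {
      g <- geneIDs[gi[j]]
      nt <- sample(seq(config@transcriptsPerGene[1],
                       config@transcriptsPerGene[2]), 1L)
      glen <- ends[j] - starts[j] + 1L
      shrink <- pmax(0L, as.integer(floor(glen * 0.1)))
      for (t in seq_len(nt)) {
        ts <- starts[j] + sample.int(shrink + 1L, 1L) - 1L
        te <- ends[j] - sample.int(shrink + 1L, 1L) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g,
          transcript_id = sprintf("%s.T%d", g, t),
          chrom = names(seqs)[cc],
          start = ts, end = te,
          strand = config@strand,
          gene_start = starts[j], gene_end = ends[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  ann <- do.call(rbind, rows)
  list(reference = seqs, annotation = ann)
}

## ---------------------------------------------------------------------
## Eligible-position index
## ---------------------------------------------------------------------

## For each of the 32 canonical (left, ref-pyrimidine, right) contexts,
## list every genomic position whose "+"-strand triplet matches the
## context or its reverse complement, with the strand-flip flag and
## the covering gene (or NA).
.contextIndex <- function(reference, annotation) {
  tab <- motifTableCached()
  ctxKey <- paste0(tab$left, tab$ref, tab$right)
  contexts <- unique(ctxKey)                     # 32 canonical triplets
  classCtx <- match(ctxKey, contexts)            # class -> context id
  revc <- function(s) chartr("ACGT", "TGCA",
                             vapply(lapply(strsplit(s, ""), rev),
                                    paste, "", collapse = ""))
  fwdOf <- setNames(seq_along(contexts), contexts)
  rcOf <- setNames(seq_along(contexts), revc(contexts))

  chromv <- posv <- ctxAll <- integer(0); flipv <- logical(0)
  genev <- character(0)
  chromNames <- names(reference)
  genes <- unique(annotation[, c("gene_id", "chrom", "gene_start",
                                 "gene_end")])
  for (ci in seq_along(reference)) {
    s <- reference[[ci]]
    L <- nchar(s)
    if (L < 3L) next
    ch <- strsplit(s, "")[[1]]
    trip <- paste0(ch[1:(L - 2L)], ch[2:(L - 1L)], ch[3:L])
    p <- 2:(L - 1L)
    fwd <- unname(fwdOf[trip]); rc <- unname(rcOf[trip])
    ctx <- ifelse(!is.na(fwd), fwd, rc)
    flip <- is.na(fwd) & !is.na(rc)
    keep <- !is.na(ctx)
    gAt <- rep(NA_character_, L)
    gg <- genes[genes$chrom == chromNames[ci], , drop = FALSE]
    for (r in seq_len(nrow(gg)))
      gAt[gg$gene_start[r]:gg$gene_end[r]] <- gg$gene_id[r]
    chromv <- c(chromv, rep.int(ci, sum(keep)))
    posv <- c(posv, p[keep])
    flipv <- c(flipv, flip[keep])
    genev <- c(genev, gAt[p[keep]])
    ctxAll <- c(ctxAll, ctx[keep])
  }
  ord <- order(ctxAll)
  byCtx <- split(ord, ctxAll[ord])
  list(chrom = chromv, pos = posv, flip = flipv, gene = genev,
       byContext = byCtx, classContext = classCtx,
       chromNames = chromNames)
}

## ---------------------------------------------------------------------
## Cohort simulation
## ---------------------------------------------------------------------

#' Simulate a somatic-mutation cohort over a generated reference
#'
#' Every sample draws a subtype, clinical attributes, exponential
#' survival with independent exponential censoring, and a Poisson
#' number of mutations. Each mutation draws a canonical motif class
#' from the sample's exposure-weighted signature mixture, then a
#' genomic position uniformly among the positions whose reference
#' trinucleotide matches the class context (on either strand); for the
#' sample's subtype, positions inside a driver (gene, motif) pair are
#' up-weighted by \code{driverBoost}. The SSM table replicates the
#' ICGC layout with one row per overlapping transcript.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param reference,annotation Output of
#'   \code{\link{generateReference}}.
#' @return List with \code{ssm} (ICGC-style data.frame), \code{clinical}
#'   (data.frame), \code{truth} (list: per-sample \code{subtype},
#'   \code{exposure} matrix, \code{driverFeatures},
#'   \code{survivalMonthsTrue}, and the per-mutation table
#'   \code{mutations} carrying the planted class label).
#' @export
simulateCohort <- function(config, reference, annotation) {
  methods::validObject(config)
  set.seed(deriveSeed(config@seed, "cohort"))
  n <- config@nSamples
  S <- config@nSubtypes
  sampleIDs <- sprintf("DO%05d", seq_len(n))
  subtype <- sample.int(S, n, replace = TRUE,
                        prob = config@subtypeProportions)

  known <- unique(annotation$gene_id)
  if (length(config@driverFeatures)) {
    drvGenes <- unlist(lapply(config@driverFeatures, `[[`, "gene"))
    if (!all(drvGenes %in% known))
      stop("driver features reference unknown gene(s): ",
           paste(setdiff(drvGenes, known), collapse = ", "))
  }

  ## clinical attributes
  sex <- character(n); project <- character(n)
  for (s in seq_len(S)) {
    i <- which(subtype == s)
    sex[i] <- sample(colnames(config@sexProbs), length(i),
                     replace = TRUE, prob = config@sexProbs[s, ])
    project[i] <- sample(colnames(config@projectProbs), length(i),
                         replace = TRUE,
                         prob = config@projectProbs[s, ])
  }
  survMonths <- rexp(n, rate = config@survivalHazards[subtype])
  censMonths <- if (config@censorRate > 0)
    rexp(n, rate = config@censorRate) else rep(Inf, n)
  obsMonths <- pmin(survMonths, censMonths)
  deceased <- survMonths <= censMonths
  obsDays <- pmax(1, round(obsMonths * 30.44))

  ## mutation counts and class draws
  mixtures <- config@plantedSignatures %*% t(config@subtypeExposures)
  nMut <- rpois(n, config@mutationsPerSampleMean)
  mutSample <- rep.int(seq_len(n), nMut)
  mutClass <- integer(length(mutSample))
  for (s in seq_len(S)) {
    i <- which(subtype[mutSample] == s)
    if (length(i))
      mutClass[i] <- sample.int(96L, length(i), replace = TRUE,
                                prob = mixtures[, s])
  }

  idx <- .contextIndex(reference, annotation)
  tab <- motifTableCached()

  ## driver lookup: per subtype, named boost genes by class index
  drvGene <- matrix(NA_character_, S, 96L)
  if (length(config@driverFeatures)) {
    for (s in seq_len(S)) {
      d <- config@driverFeatures[[s]]
      if (!is.null(d) && nrow(d)) {
        ci <- match(d$motif, motifClassLabels())
        if (anyNA(ci)) stop("unknown driver motif label")
        drvGene[s, ci] <- d$gene
      }
    }
  }

  chosen <- integer(length(mutSample))   # row index into context pool
  maxRetry <- 10L
  for (attempt in seq_len(maxRetry)) {
    todo <- which(chosen == 0L)
    if (!length(todo)) break
    grp <- split(todo, list(subtype[mutSample[todo]], mutClass[todo]),
                 drop = TRUE)
    resampled <- FALSE
    for (gname in names(grp)) {
      g <- grp[[gname]]
      s <- subtype[mutSample[g[1]]]
      cl <- mutClass[g[1]]
      ctx <- idx$classContext[cl]
      pool <- idx$byContext[[as.character(ctx)]]
      if (is.null(pool) || !length(pool)) {
        ## no eligible position genome-wide: redraw the class
        for (m in g)
          mutClass[m] <- sample.int(96L, 1L, prob = mixtures[, s])
        resampled <- TRUE
        next
      }
      bg <- drvGene[s, cl]
      if (!is.na(bg)) {
        w <- 1 + (config@driverBoost - 1) *
          (!is.na(idx$gene[pool]) & idx$gene[pool] == bg)
        chosen[g] <- pool[sample.int(length(pool), length(g),
                                     replace = TRUE, prob = w)]
      } else {
        chosen[g] <- pool[sample.int(length(pool), length(g),
                                     replace = TRUE)]
      }
    }
    if (!resampled && all(chosen != 0L)) break
    if (attempt == maxRetry && any(chosen == 0L))
      stop("could not place mutations: motif class with no eligible ",
           "positions after ", maxRetry, " resampling rounds")
  }

  flip <- idx$flip[chosen]
  refB <- ifelse(flip, complementBase(tab$ref[mutClass]),
                 tab$ref[mutClass])
  altB <- ifelse(flip, complementBase(tab$alt[mutClass]),
                 tab$alt[mutClass])
  mutations <- data.frame(
    sample_id = sampleIDs[mutSample],
    chrom = idx$chromNames[idx$chrom[chosen]],
    pos = idx$pos[chosen],
    ref = refB, alt = altB,
    gene_id = ifelse(is.na(idx$gene[chosen]), "", idx$gene[chosen]),
    class = motifClassLabels()[mutClass],
    subtype = subtype[mutSample],
    stringsAsFactors = FALSE)

  ## one SSM row per overlapping transcript (ICGC dialect); intergenic
  ## mutations and genic positions outside every transcript get one row
  ssm <- .expandTranscriptRows(mutations, annotation)

  clinical <- data.frame(
    icgc_donor_id = sampleIDs,
    donor_sex = sex,
    project_code = project,
    donor_vital_status = ifelse(deceased, "deceased", "alive"),
    donor_survival_time = obsDays,
    stage = paste0("stage", ((subtype + seq_len(n)) %% 4L) + 1L),
    grade = paste0("G", ((seq_len(n)) %% 3L) + 1L),
    stringsAsFactors = FALSE)

  truth <- list(
    sample_id = sampleIDs,
    subtype = subtype,
    exposure = config@subtypeExposures[subtype, , drop = FALSE],
    driverFeatures = config@driverFeatures,
    survivalMonthsTrue = survMonths,
    mutations = mutations)

  list(ssm = ssm, clinical = clinical, truth = truth)
}

.expandTranscriptRows <- function(mutations, annotation) {
  m <- mutations
  tr <- annotation
  genic <- which(m$gene_id != "")
  rowsPerTx <- NULL
  if (length(genic)) {
    mg <- data.frame(i = genic, gene_id = m$gene_id[genic],
                     pos = m$pos[genic], stringsAsFactors = FALSE)
    j <- merge(mg, tr[, c("gene_id", "transcript_id", "start", "end")],
               by = "gene_id")
    j <- j[j$start <= j$pos & j$end >= j$pos, , drop = FALSE]
    covered <- unique(j$i)
    uncov <- setdiff(genic, covered)
    rowsPerTx <- data.frame(
      i = c(j$i, uncov),
      transcript_id = c(j$transcript_id, rep("", length(uncov))),
      consequence = c(rep("transcript_variant", nrow(j)),
                      rep("intragenic_variant", length(uncov))),
      stringsAsFactors = FALSE)
  }
  inter <- which(m$gene_id == "")
  if (length(inter))
    rowsPerTx <- rbind(rowsPerTx, data.frame(
      i = inter, transcript_id = "",
      consequence = "intergenic_region", stringsAsFactors = FALSE))
  rowsPerTx <- rowsPerTx[order(rowsPerTx$i, rowsPerTx$transcript_id), ,
                         drop = FALSE]
  i <- rowsPerTx$i
  data.frame(
    icgc_donor_id = m$sample_id[i],
    chromosome = m$chrom[i],
    chromosome_start = m$pos[i],
    chromosome_end = m$pos[i],
    reference_genome_allele = m$ref[i],
    mutated_to_allele = m$alt[i],
    gene_affected = m$gene_id[i],
    transcript_affected = rowsPerTx$transcript_id,
    consequence_type = rowsPerTx$consequence,
    stringsAsFactors = FALSE)
}

#' Write a complete synthetic study to a directory
#'
#' Generates the reference and cohort and writes
#' \code{reference.fa}, \code{annotation.tsv}, \code{ssm.tsv},
#' \code{clinical.tsv} and \code{truth.json}.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulateStudy <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  refout <- generateReference(config)
  cohort <- simulateCohort(config, refout$reference, refout$annotation)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    annotation = file.path(dir, "annotation.tsv"),
    ssm = file.path(dir, "ssm.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(refout$reference), paths$reference)
  write.table(refout$annotation, paths$annotation, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$ssm, paths$ssm, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$clinical, paths$clinical, sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$exposure <- unname(apply(truth$exposure, 1, as.numeric,
                                 simplify = FALSE))
  truth$mutations <- NULL   # regenerable; keep the JSON small
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(list(reference = refout$reference,
                   annotation = refout$annotation), cohort,
              list(paths = paths)))
}

#' Simulate a 96-class catalog matrix directly from signatures
#'
#' Draws each sample's exposure-weighted signature mixture and a
#' multinomial class count vector, bypassing the genomic placement
#' machinery. Used for signature-recovery studies where only the
#' catalog matters.
#'
#' @param signatures 96 x k column-stochastic matrix.
#' @param exposures nSamples x k row-stochastic matrix (one row per
#'   sample), or k-vector applied to all samples.
#' @param mutationsPerSample Integer scalar or vector of per-sample
#'   totals.
#' @param seed Integer seed.
#' @return 96 x nSamples integer matrix in canonical class order.
#' @export
simulateCatalogMatrix <- function(signatures, exposures,
                                  mutationsPerSample, seed = 1L) {
  if (is.null(dim(exposures)))
    exposures <- matrix(exposures, 1, length(exposures))
  nS <- nrow(exposures)
  if (nS == 1L && length(mutationsPerSample) > 1L) {
    exposures <- exposures[rep(1L, length(mutationsPerSample)), ,
                           drop = FALSE]
    nS <- nrow(exposures)
  }
  tot <- rep_len(mutationsPerSample, nS)
  set.seed(deriveSeed(seed, "catalog"))
  M <- matrix(0L, 96L, nS,
              dimnames = list(motifClassLabels(),
                              sprintf("S%04d", seq_len(nS))))
  for (j in seq_len(nS)) {
    p <- as.numeric(signatures %*% exposures[j, ])
    M[, j] <- as.integer(rmultinom(1, tot[j], p))
  }
  M
}
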