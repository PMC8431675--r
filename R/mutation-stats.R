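#' @importFrom stats dhyper pchisq pt rbinom
NULL

#' Per-subtype mutation-rate table
#'
#' Entry (s, item) is the fraction of samples labelled s carrying at
#' least one mutation in the item (gene, gene-motif or transcript).
#' Outlier samples must be excluded from \code{labels} beforehand.
#'
#' @param labels Named character vector sample -> subtype label.
#' @param presence Binary matrix samples x items (rownames = sample
#'   IDs).
#' @return List with \code{rates} (subtypes x items) and \code{sizes}
#'   (named subtype sizes).
#' @export
rateTable <- function(labels, presence) {
  presence <- as.matrix(presence)
  if (is.null(names(labels)))
    stop("labels must be named by sample ID")
  common <- intersect(names(labels), rownames(presence))
  if (!length(common)) stop("labels and presence share no samples")
  labels <- labels[common]
  presence <- presence[common, , drop = FALSE]
  groups <- sort(unique(labels))
  sizes <- table(labels)[groups]
  if (any(sizes == 0)) stop("empty subtype")
  rates <- t(vapply(groups, function(g)
    colMeans(presence[labels == g, , drop = FALSE] >= 1),
    numeric(ncol(presence))))
  if (ncol(presence) == 1L) {
    rates <- matrix(rates, nrow = length(groups),
                    dimnames = list(groups, colnames(presence)))
  } else rownames(rates) <- groups
  list(rates = rates, sizes = setNames(as.integer(sizes), groups))
}

#' Pairwise signed differences of subtype rates
#'
#' @param table Result of \code{\link{rateTable}}.
#' @return Long-format data.frame with columns \code{subtype_a,
#'   subtype_b, item, diff} where \code{diff = rate_a - rate_b}
#'   (antisymmetric in the pair).
#' @export
differentialRates <- function(table) {
  r <- table$rates
  groups <- rownames(r)
  if (length(groups) < 2L) stop("need at least 2 subtypes")
  out <- list()
  for (a in groups) for (b in groups) {
    if (a == b) next
    out[[length(out) + 1L]] <- data.frame(
      subtype_a = a, subtype_b = b, item = colnames(r),
      diff = r[a, ] - r[b, ], row.names = NULL,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Welch two-sample t-test on mutation-rate vectors
#'
#' Unequal-variance (Welch) two-sided t-test with
#' Welch-Satterthwaite degrees of freedom, comparing the mean
#' per-item mutation rates of two subtypes.
#'
#' @param ratesA,ratesB Numeric vectors over the same items.
#' @return List with \code{t}, \code{df}, \code{p} and a
#'   \code{degenerate} flag (both variances zero with unequal means).
#' @export
rateTTest <- function(ratesA, ratesB) {
  if (length(ratesA) != length(ratesB) || length(ratesA) < 2L)
    stop("rate vectors must have equal length >= 2")
  va <- var(ratesA); vb <- var(ratesB)
  na <- length(ratesA); nb <- length(ratesB)
  if (va == 0 && vb == 0) {
    if (mean(ratesA) == mean(ratesB))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(ratesA) - mean(ratesB)) * Inf,
                df = NA_real_, p = 0, degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- (mean(ratesA) - mean(ratesB)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric
#' probabilities of all tables at most as probable as the observed one
#' (with a 1e-7 relative slack on the comparison, as in the classical
#' implementation).
#'
#' @param a,b,c,d Nonnegative integer cells, table
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return Two-sided p-value.
#' @examples
#' fisherExact2x2(10, 0, 0, 10)
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be nonnegative integers")
  if (sum(cells) == 0) return(1)
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  K <- a + c          # column 1 total
  lo <- max(0L, K - n2); hi <- min(K, m)
  x <- lo:hi
  probs <- dhyper(x, m, n2, K)
  pobs <- dhyper(a, m, n2, K)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

## Vectorised Fisher p for x mutated of nA vs y mutated of nB, with
## memoisation over the (x, y) grid - the permutation loop hits the
## same tables repeatedly.
.fisherGrid <- function(x, y, nA, nB, cache = NULL) {
  key <- x * (nB + 1L) + y
  p <- rep(NA_real_, length(x))
  if (!is.null(cache)) {
    hit <- !is.na(cache[key + 1L])
    p[hit] <- cache[key + 1L][hit]
  } else hit <- rep(FALSE, length(x))
  todo <- which(!hit)
  for (i in todo) {
    p[i] <- fisherExact2x2(x[i], nA - x[i], y[i], nB - y[i])
    if (!is.null(cache)) cache[key[i] + 1L] <- p[i]
  }
  if (!is.null(cache)) list(p = p, cache = cache) else p
}

## Uniform multinomial draw over G genes with a per-gene cap: draws
## landing on a gene already at the cap (the subtype size) are
## resampled among genes with remaining capacity.
.multinomialCapped <- function(total, G, cap) {
  total <- as.integer(total); cap <- as.integer(cap)
  if (total > as.numeric(G) * cap)
    stop("total count exceeds G * subtype size")
  cnt <- as.integer(rmultinom(1, total, rep(1 / G, G)))
  repeat {
    over <- cnt > cap
    if (!any(over)) break
    excess <- sum(cnt[over] - cap)
    cnt[over] <- cap
    open <- which(cnt < cap)
    add <- tabulate(sample.int(length(open), excess, replace = TRUE),
                    nbins = length(open))
    cnt[open] <- cnt[open] + add
  }
  cnt
}

#' Permutation-derived significance thresholds for gene association
#'
#' For every permutation, per-gene mutated-sample counts are
#' regenerated for each subtype while preserving that subtype's total
#' count, Fisher tests are recomputed for every gene, and after
#' \code{nPerm} repetitions each (gene, subtype) pair holds
#' \code{nPerm} null p-values; its threshold is the p-value at rank
#' \code{ceiling(tailFrac * nPerm)} of the sorted null values (the
#' lowest 0.05 percent at the default 10,000 x 0.0005, i.e. rank 5).
#'
#' @param observedCounts Integer matrix subtypes x genes: number of
#'   mutated samples per gene per subtype.
#' @param subtypeSizes Named integer vector of subtype sizes.
#' @param nPerm Number of permutations (default 10000).
#' @param tailFrac Tail fraction (default 0.0005);
#'   \code{nPerm * tailFrac >= 1} is required.
#' @param scheme \code{"multinomial_uniform"} (counts redrawn
#'   multinomially over genes with uniform probabilities, redrawing
#'   draws exceeding the subtype size) or \code{"count_permutation"}
#'   (observed counts permuted over gene labels).
#' @param seed Integer seed.
#' @param pooled Pool null p-values over subtypes, giving one
#'   threshold per gene (default FALSE: per gene x subtype).
#' @return List with \code{thresholds} (subtypes x genes, or 1 x genes
#'   if pooled), \code{observedP} (subtypes x genes Fisher p-values),
#'   \code{rank} (the tail rank used).
#' @export
permutationThresholds <- function(observedCounts, subtypeSizes,
                                  nPerm = 10000L, tailFrac = 5e-4,
                                  scheme = c("multinomial_uniform",
                                             "count_permutation"),
                                  seed = 1L, pooled = FALSE) {
  scheme <- match.arg(scheme)
  if (nPerm * tailFrac < 1)
    stop("nPerm * tailFrac must be at least 1")
  counts <- as.matrix(observedCounts)
  S <- nrow(counts); G <- ncol(counts)
  sizes <- as.integer(subtypeSizes)
  if (length(sizes) != S) stop("one size per subtype is required")
  nTotal <- sum(sizes)
  rank <- as.integer(ceiling(tailFrac * nPerm))

  caches <- lapply(seq_len(S), function(s)
    rep(NA_real_, (sizes[s] + 1L) * (nTotal - sizes[s] + 1L)))

  pFor <- function(cnt) {
    ## cnt: S x G count matrix; returns S x G Fisher p matrix
    out <- matrix(NA_real_, S, G)
    for (s in seq_len(S)) {
      x <- cnt[s, ]
      y <- colSums(cnt[-s, , drop = FALSE])
      y <- pmin(y, nTotal - sizes[s])   # guard against over-counts
      res <- .fisherGrid(x, y, sizes[s], nTotal - sizes[s], caches[[s]])
      caches[[s]] <<- res$cache
      out[s, ] <- res$p
    }
    out
  }

  observedP <- pFor(counts)
  dimnames(observedP) <- dimnames(counts)

  set.seed(deriveSeed(seed, "permutation-thresholds"))
  totals <- rowSums(counts)
  nullP <- array(NA_real_, c(nPerm, S, G))
  for (b in seq_len(nPerm)) {
    cnt <- matrix(0L, S, G)
    for (s in seq_len(S)) {
      if (scheme == "multinomial_uniform") {
        cnt[s, ] <- .multinomialCapped(totals[s], G, sizes[s])
      } else {
        cnt[s, ] <- counts[s, sample.int(G)]
      }
    }
    nullP[b, , ] <- pFor(cnt)
  }

  if (pooled) {
    thr <- matrix(NA_real_, 1L, G)
    poolRank <- as.integer(ceiling(tailFrac * nPerm * S))
    for (g in seq_len(G))
      thr[1L, g] <- sort(as.numeric(nullP[, , g]))[poolRank]
  } else {
    thr <- matrix(NA_real_, S, G)
    for (s in seq_len(S)) for (g in seq_len(G))
      thr[s, g] <- sort(nullP[, s, g])[rank]
    dimnames(thr) <- dimnames(counts)
  }
  list(thresholds = thr, observedP = observedP, rank = rank)
}

#' Call genes associated with subtypes
#'
#' A gene is associated with a subtype when its Fisher p-value falls
#' below the permutation-derived threshold and the gene is mutated in
#' at least 50 percent of the subtype's samples (inclusive).
#'
#' @param rates Subtypes x genes rate matrix (fractions of mutated
#'   samples), as from \code{\link{rateTable}}.
#' @param pValues Subtypes x genes observed Fisher p-values.
#' @param thresholds Subtypes x genes (or 1 x genes pooled) threshold
#'   matrix.
#' @param rateCutoff Minimum subtype mutation rate (default 0.5).
#' @return data.frame with columns \code{subtype, gene, p, threshold,
#'   rate, associated}.
#' @export
associateGenes <- function(rates, pValues, thresholds,
                           rateCutoff = 0.5) {
  S <- nrow(pValues); G <- ncol(pValues)
  if (nrow(thresholds) == 1L && S > 1L)
    thresholds <- thresholds[rep(1L, S), , drop = FALSE]
  stopifnot(identical(dim(rates), dim(pValues)),
            identical(dim(thresholds), dim(pValues)))
  out <- expand.grid(subtype = rownames(pValues),
                     gene = colnames(pValues),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$p <- as.numeric(pValues[cbind(
    match(out$subtype, rownames(pValues)),
    match(out$gene, colnames(pValues)))])
  idx <- cbind(match(out$subtype, rownames(pValues)),
               match(out$gene, colnames(pValues)))
  out$threshold <- as.numeric(thresholds[idx])
  out$rate <- as.numeric(rates[idx])
  out$associated <- out$p < out$threshold & out$rate >= rateCutoff
  out
}

#' Fisher test of motif preference between two subtypes
#'
#' Restricting to samples of two subtypes, tests the 2x2 association
#' of subtype membership against carrying a given gene-motif.
#'
#' @param geneMotifs A \linkS4class{GeneMotifExperiment}.
#' @param feature Gene-motif label, e.g. \code{"GENE0001-TA-A.A"}.
#' @param labels Named subtype labels.
#' @param subtypeA,subtypeB Subtype labels to compare.
#' @return List with the 2x2 \code{table} and two-sided \code{p}.
#' @export
motifPreferenceTest <- function(geneMotifs, feature, labels,
                                subtypeA, subtypeB) {
  occ <- occurrence(geneMotifs)
  if (!feature %in% rownames(occ))
    stop("gene-motif not in matrix: ", feature)
  inA <- names(labels)[labels == subtypeA]
  inB <- names(labels)[labels == subtypeB]
  if (!length(inA) || !length(inB)) stop("both subtypes must be nonempty")
  inA <- intersect(inA, colnames(occ))
  inB <- intersect(inB, colnames(occ))
  hasA <- sum(occ[feature, inA] >= 1)
  hasB <- sum(occ[feature, inB] >= 1)
  tab <- rbind(c(hasA, length(inA) - hasA),
               c(hasB, length(inB) - hasB))
  dimnames(tab) <- list(c(subtypeA, subtypeB), c("has", "lacks"))
  list(table = tab,
       p = fisherExact2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}

#' Per-subtype transcript mutation rates
#'
#' Fraction of each subtype's samples with at least one mutation
#' annotated to each transcript (using the full transcript-row list,
#' before deduplication across transcripts).
#'
#' @param cohort A \linkS4class{MutationCohort}.
#' @param labels Named subtype labels (outliers excluded).
#' @return As \code{\link{rateTable}}: list with \code{rates}
#'   (subtypes x transcripts) and \code{sizes}.
#' @export
transcriptRates <- function(cohort, labels) {
  hits <- cohort@transcriptHits
  hits <- unique(hits[, c("sample_id", "transcript_id")])
  txs <- sort(unique(hits$transcript_id))
  samples <- names(labels)
  pres <- matrix(0L, length(samples), length(txs),
                 dimnames = list(samples, txs))
  hits <- hits[hits$sample_id %in% samples, , drop = FALSE]
  pres[cbind(match(hits$sample_id, samples),
             match(hits$transcript_id, txs))] <- 1L
  rateTable(labels, pres)
}
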