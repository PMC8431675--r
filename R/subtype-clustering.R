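#' @importFrom stats var
NULL

#' Meaningful-cluster size threshold
#'
#' A cluster is meaningful when it holds at least 1 percent of the
#' cohort, with an absolute floor (7 in a 774-sample cohort:
#' \code{max(7, floor(0.01 * 774)) = 7}).
#'
#' @param n Total number of samples.
#' @param minFrac Fraction of the cohort (default 0.01).
#' @param minAbs Absolute floor (default 7).
#' @return Integer threshold.
#' @examples
#' meaningfulMinSize(774)  # 7
#' @export
meaningfulMinSize <- function(n, minFrac = 0.01, minAbs = 7L) {
  max(as.integer(minAbs), as.integer(floor(minFrac * n)))
}

#' Recursive model-based clustering with the meaningful-cluster rule
#'
#' Clusters the candidate-feature matrix with a BIC-selected Gaussian
#' mixture, applied recursively: a cluster is meaningful if it holds
#' at least \code{max(minAbs, floor(minFrac * n_total))} samples;
#' smaller clusters found at the first round become outliers, and a
#' recursive split of an existing cluster is accepted only when it
#' produces at least two meaningful subclusters (members of sub-split
#' fragments below the threshold then become outliers). Recursion
#' proceeds on the same global feature columns until no node splits.
#' Leaves are labelled \code{PCS1, PCS2, ...} in decreasing size
#' order.
#'
#' @param X Numeric matrix, samples x candidate features (binary
#'   occurrence values are used as real 0/1), rownames = sample IDs.
#' @param minFrac Meaningful-cluster fraction of the total cohort
#'   (default 0.01).
#' @param minAbs Absolute floor on the meaningful-cluster size
#'   (default 7).
#' @param kRange Candidate component counts per node (default 1:9).
#' @param model Covariance family, see \code{\link{fitGmm}}.
#' @param seed Integer seed.
#' @param varFloor Variance floor passed to \code{\link{fitGmm}}. The
#'   default 0.05 -- the variance of a binary feature whose minority
#'   value occurs in about 5 percent of a cluster -- treats features
#'   that are effectively constant within a cluster as uninformative.
#'   On 0/1 occurrence data a near-zero floor lets a component that is
#'   exactly constant in some feature claim an unbounded likelihood
#'   gain, the degenerate solutions that Mclust-style fitting discards
#'   as singular; the floor plays that role here.
#' @return A \linkS4class{SubtypeTree}.
#' @export
recursiveCluster <- function(X, minFrac = 0.01, minAbs = 7L,
                             kRange = 1:9,
                             model = c("diagonal", "spherical"),
                             seed = 1L, varFloor = 0.05) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (is.null(rownames(X)))
    rownames(X) <- sprintf("sample%04d", seq_len(nrow(X)))
  n <- nrow(X)
  minSize <- meaningfulMinSize(n, minFrac, minAbs)
  labels <- rep(NA_character_, n)
  nodes <- list()
  leafSets <- list()
  outlier <- integer(0)

  if (n < minSize) {
    labels[] <- "PCS1"
    return(methods::new("SubtypeTree", labels = labels,
                        sampleIDs = rownames(X),
                        nodes = list(list(id = "root", n = n,
                                          status = "leaf_small_cohort")),
                        minSize = as.integer(minSize)))
  }

  recurse <- function(idx, nodeID, depth, isRoot) {
    sub <- X[idx, , drop = FALSE]
    fit <- tryCatch(
      selectK(sub, kRange = kRange, model = model,
              seed = deriveSeed(seed, nodeID), varFloor = varFloor),
      error = function(e) NULL)
    rec <- list(id = nodeID, n = length(idx), depth = depth)
    if (is.null(fit) || fit@k == 1L) {
      rec$status <- "leaf"
      rec$k <- if (is.null(fit)) NA_integer_ else fit@k
      nodes[[length(nodes) + 1L]] <<- rec
      leafSets[[length(leafSets) + 1L]] <<- idx
      return(invisible(NULL))
    }
    cl <- fit@classification
    sizes <- tabulate(cl, nbins = fit@k)
    meaningful <- which(sizes >= minSize)
    rec$k <- fit@k
    rec$sizes <- sizes
    rec$bicTable <- attr(fit, "bicTable")
    accepted <- if (isRoot) length(meaningful) >= 1L else
      length(meaningful) >= 2L
    if (!accepted) {
      rec$status <- "leaf"
      nodes[[length(nodes) + 1L]] <<- rec
      leafSets[[length(leafSets) + 1L]] <<- idx
      return(invisible(NULL))
    }
    rec$status <- "split"
    nodes[[length(nodes) + 1L]] <<- rec
    small <- setdiff(seq_len(fit@k), meaningful)
    if (length(small))
      outlier <<- c(outlier, idx[cl %in% small])
    for (j in meaningful)
      recurse(idx[cl == j], sprintf("%s.%d", nodeID, j), depth + 1L,
              isRoot = FALSE)
    invisible(NULL)
  }

  recurse(seq_len(n), "root", 0L, isRoot = TRUE)

  ord <- order(vapply(leafSets, length, 0L), decreasing = TRUE)
  for (i in seq_along(ord))
    labels[leafSets[[ord[i]]]] <- paste0("PCS", i)
  labels[outlier] <- "OUTLIER"
  methods::new("SubtypeTree", labels = labels, sampleIDs = rownames(X),
               nodes = nodes, minSize = as.integer(minSize))
}

#' Principal-component projection diagnostic
#'
#' Column-centred SVD projection with a deterministic sign convention:
#' each component's largest-magnitude loading is made positive.
#'
#' @param X Numeric matrix, samples x features.
#' @param nComponents Number of components to return (default 2).
#' @return List with \code{coordinates} (samples x components),
#'   \code{explainedVariance} (fractions), \code{loadings}.
#' @export
pcaProject <- function(X, nComponents = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(nc), drop = FALSE]
  coords <- pc$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ev <- pc$sdev^2
  list(coordinates = coords,
       explainedVariance = ev[seq_len(nc)] / sum(ev),
       loadings = rot)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same
#' samples; 1 means identical partitions, 0 is the expectation under
#' independent random partitions.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  nPairs <- comb2(length(a))
  expected <- sumI * sumJ / nPairs
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}
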