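#' @importFrom cluster pam silhouette
#' @importFrom pracma lsqnonneg
NULL

## generalized Kullback-Leibler divergence D(V || WH)
.klDivergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' Non-negative matrix factorisation by multiplicative KL updates
#'
#' Minimises the generalized Kullback-Leibler divergence between the
#' 96 x S catalog and W H using the classical multiplicative update
#' rules from a seeded uniform-random initialisation. The KL objective
#' matches the Poisson character of mutation counts. On return W is
#' column-normalised with the scale folded into H.
#'
#' @param M Nonnegative 96 x S matrix of class counts.
#' @param k Factorisation rank, 1 <= k <= min(96, S).
#' @param seed Integer seed.
#' @param maxIter Iteration cap (default 2000).
#' @param tol Relative divergence-change tolerance (default 1e-6).
#' @return List with \code{W} (96 x k, columns sum to 1), \code{H}
#'   (k x S), \code{divergence}, \code{iterations},
#'   \code{trace} (divergence per check).
#' @export
nmfKL <- function(M, k, seed = 1L, maxIter = 2000L, tol = 1e-6) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("M must be nonnegative")
  if (sum(M) == 0) stop("M must not be all zero")
  n <- nrow(M); S <- ncol(M)
  if (k < 1L || k > min(n, S)) stop("need 1 <= k <= min(dim(M))")
  zeroCol <- colSums(M) == 0
  if (any(zeroCol))
    warning(sum(zeroCol), " all-zero sample column(s): exposures ",
            "will be zero", call. = FALSE)
  set.seed(deriveSeed(seed, sprintf("nmf-k%d", k)))
  eps <- .Machine$double.eps
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * S, 0.1, 1), k, S)
  WH <- W %*% H
  div <- .klDivergence(M, WH)
  trace <- div
  it <- 0L
  for (it in seq_len(maxIter)) {
    ## H update
    R <- M / pmax(WH, eps)
    H <- H * (crossprod(W, R) / pmax(colSums(W), eps))
    WH <- W %*% H
    ## W update
    R <- M / pmax(WH, eps)
    W <- W * ((R %*% t(H)) / pmax(rep(rowSums(H), each = n), eps))
    WH <- W %*% H
    newDiv <- .klDivergence(M, WH)
    if (it %% 10L == 0L || newDiv <= tol) trace <- c(trace, newDiv)
    if (abs(div - newDiv) < tol * max(abs(div), eps)) {
      div <- newDiv
      break
    }
    div <- newDiv
  }
  scale <- colSums(W)
  scale[scale == 0] <- 1
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  list(W = W, H = H, divergence = div, iterations = it, trace = trace)
}

.cosineSim <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)) + 1e-300, "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)) + 1e-300, "/")
  crossprod(An, Bn)
}

#' Decipher consensus signatures by bootstrap NMF
#'
#' Each bootstrap resamples every sample's class counts multinomially
#' (preserving its mutation burden), factorises the resampled catalog,
#' and pools the resulting signatures; the pool is partitioned into k
#' groups by k-medoids under cosine distance. Consensus signatures are
#' the normalised medoids; per-group silhouette widths measure
#' stability; exposures are refit on the original catalog by
#' non-negative least squares.
#'
#' @param M Nonnegative 96 x S count matrix (rows in canonical class
#'   order; a \linkS4class{MotifCatalog} is also accepted).
#' @param k Number of signatures.
#' @param nBoot Bootstrap iterations (>= 2; desk default 50).
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{nmfKL}}.
#' @return A \linkS4class{SignatureSet}.
#' @export
decipherSignatures <- function(M, k, nBoot = 50L, seed = 1L, ...) {
  if (methods::is(M, "MotifCatalog")) M <- motifCounts(M)
  M <- as.matrix(M)
  if (nBoot < 2L) stop("nBoot must be at least 2")
  S <- ncol(M)
  set.seed(deriveSeed(seed, "decipher-boot"))
  totals <- colSums(M)
  pool <- matrix(NA_real_, nrow(M), nBoot * k)
  for (b in seq_len(nBoot)) {
    Mb <- M
    for (j in seq_len(S)) {
      if (totals[j] > 0)
        Mb[, j] <- as.integer(rmultinom(1, totals[j],
                                        M[, j] / totals[j]))
    }
    fit <- nmfKL(Mb, k, seed = deriveSeed(seed, sprintf("boot%d", b)),
                 ...)
    pool[, (b - 1L) * k + seq_len(k)] <- fit$W
  }

  if (k == 1L) {
    ## single group: stability is mean cosine similarity to the medoid
    d <- 1 - .cosineSim(pool, pool)
    med <- which.min(colSums(d))
    sil <- 1 - mean(d[, med])
    W <- pool[, med, drop = FALSE] / sum(pool[, med])
    sils <- sil
  } else {
    d <- 1 - .cosineSim(pool, pool)
    d[d < 0] <- 0
    pm <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
    W <- pool[, pm$id.med, drop = FALSE]
    W <- sweep(W, 2, colSums(W), "/")
    silObj <- cluster::silhouette(pm$clustering, stats::as.dist(d))
    sils <- vapply(seq_len(k), function(g)
      mean(silObj[silObj[, "cluster"] == g, "sil_width"]), 0)
  }
  rownames(W) <- motifClassLabels()
  colnames(W) <- paste0("Signature", seq_len(k))

  H <- fitExposures(M, W)
  recon <- sqrt(sum((M - W %*% H$absolute)^2))
  methods::new("SignatureSet",
    signatures = W,
    exposures = H$absolute,
    relativeExposures = H$relative,
    silhouette = as.numeric(sils),
    meanSilhouette = mean(sils),
    reconstructionError = recon,
    k = as.integer(k))
}

#' Sweep the number of signatures and report diagnostics
#'
#' Runs \code{\link{decipherSignatures}} over a range of k and tables
#' mean silhouette and reconstruction error (the model-selection
#' "evaluation plot" data). The automatic suggestion is the largest k
#' whose mean silhouette is at least \code{silCut}; the choice is
#' user-overridable.
#'
#' @inheritParams decipherSignatures
#' @param kRange Candidate signature counts (desk default 1:6).
#' @param silCut Silhouette cut for the suggestion (default 0.8).
#' @return List with \code{table} (k, meanSilhouette,
#'   reconstructionError), \code{suggestion}, \code{fits} (per-k
#'   \linkS4class{SignatureSet}s).
#' @export
sweepSignatureK <- function(M, kRange = 1:6, nBoot = 50L, seed = 1L,
                            silCut = 0.8, ...) {
  if (methods::is(M, "MotifCatalog")) M <- motifCounts(M)
  kRange <- sort(unique(as.integer(kRange)))
  fits <- list()
  tab <- data.frame(k = kRange, meanSilhouette = NA_real_,
                    reconstructionError = NA_real_)
  for (i in seq_along(kRange)) {
    fits[[i]] <- decipherSignatures(M, kRange[i], nBoot = nBoot,
                                    seed = seed, ...)
    tab$meanSilhouette[i] <- fits[[i]]@meanSilhouette
    tab$reconstructionError[i] <- fits[[i]]@reconstructionError
  }
  ok <- which(tab$meanSilhouette >= silCut)
  suggestion <- if (length(ok)) max(tab$k[ok]) else min(tab$k)
  list(table = tab, suggestion = suggestion, fits = fits)
}

#' Fit per-sample exposures by non-negative least squares
#'
#' @param M 96 x S counts (or \linkS4class{MotifCatalog}).
#' @param W 96 x k signature matrix.
#' @return List with \code{absolute} (k x S) and \code{relative}
#'   (columns normalised to 1; zero-mutation samples stay zero).
#' @export
fitExposures <- function(M, W) {
  if (methods::is(M, "MotifCatalog")) M <- motifCounts(M)
  M <- as.matrix(M); W <- as.matrix(W)
  S <- ncol(M); k <- ncol(W)
  H <- matrix(0, k, S, dimnames = list(colnames(W), colnames(M)))
  for (j in seq_len(S)) {
    if (sum(M[, j]) == 0) next
    H[, j] <- pracma::lsqnonneg(W, M[, j])$x
  }
  tot <- colSums(H)
  rel <- sweep(H, 2, ifelse(tot > 0, tot, 1), "/")
  list(absolute = H, relative = rel)
}

#' Compare deciphered signatures with a reference catalog
#'
#' Computes pairwise cosine similarity (or the normalised-angle
#' "angular" similarity \code{1 - (2/pi) * acos(cos)}) between
#' signatures and a reference catalog, and lists best matches above
#' the threshold.
#'
#' @param W 96 x k signature matrix (or \linkS4class{SignatureSet}).
#' @param reference 96 x K reference matrix from
#'   \code{\link{readSignatureCatalog}}.
#' @param metric \code{"cosine"} (default) or \code{"angular"}.
#' @param threshold Match threshold (default 0.70).
#' @return List with \code{similarity} (k x K), \code{matches}
#'   (data.frame signature, reference, similarity, matched),
#'   \code{metric}.
#' @export
compareToReference <- function(W, reference, metric = c("cosine",
                                                        "angular"),
                               threshold = 0.70) {
  metric <- match.arg(metric)
  if (methods::is(W, "SignatureSet")) W <- signatures(W)
  if (!identical(rownames(W), rownames(reference)) &&
      !is.null(rownames(W)) && !is.null(rownames(reference)))
    reference <- reference[rownames(W), , drop = FALSE]
  sim <- .cosineSim(as.matrix(W), as.matrix(reference))
  if (metric == "angular")
    sim <- 1 - (2 / pi) * acos(pmin(pmax(sim, -1), 1))
  best <- max.col(sim)
  matches <- data.frame(
    signature = colnames(W) %||% paste0("Signature", seq_len(ncol(W))),
    reference = colnames(reference)[best] %||% as.character(best),
    similarity = sim[cbind(seq_len(nrow(sim)), best)],
    stringsAsFactors = FALSE)
  matches$matched <- matches$similarity > threshold
  list(similarity = sim, matches = matches, metric = metric)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
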