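#' @importFrom stats kmeans prcomp
NULL

## squared Euclidean distances from rows of X to a single center
.sqDist <- function(X, center) {
  sweep(X, 2, center)^2 |> rowSums()
}

## k-means++ center choice from a seeded RNG (RNG state managed by the
## caller)
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  if (k > 1L) {
    d2 <- .sqDist(X, centers[1L, ])
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1L, prob = p)
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, .sqDist(X, centers[j, ]))
    }
  }
  centers
}

## per-component diagonal-Gaussian log densities, n x k
.logDens <- function(X, means, variances, weights) {
  n <- nrow(X); k <- nrow(means); d <- ncol(X)
  Vinv <- 1 / variances
  quad <- X^2 %*% t(Vinv) - 2 * X %*% t(means * Vinv)
  quad <- sweep(quad, 2, rowSums(means^2 * Vinv), "+")
  logdet <- rowSums(log(variances))
  ld <- -0.5 * (d * log(2 * pi) + rep(logdet, each = n) + quad)
  sweep(ld, 2, log(weights), "+")
}

.mstep <- function(X, r, model, varFloor) {
  n <- nrow(X); d <- ncol(X)
  Nj <- colSums(r)
  weights <- Nj / n
  means <- (t(r) %*% X) / Nj
  ex2 <- (t(r) %*% (X^2)) / Nj
  vars <- ex2 - means^2
  if (model == "spherical") {
    v <- rowMeans(vars)
    vars <- matrix(v, nrow(vars), d)
  }
  vars <- pmax(vars, varFloor)
  list(weights = weights, means = means, variances = vars, Nj = Nj)
}

#' Fit a diagonal or spherical Gaussian mixture by EM
#'
#' EM from a seeded k-means++ initialisation, best of \code{nInit}
#' restarts by log-likelihood. Convergence is declared when the
#' relative log-likelihood change drops below \code{tol}; per-dimension
#' variances are floored at \code{varFloor}. An emptied component is
#' re-initialised from the point farthest from its nearest surviving
#' component (at most 3 rescues per restart).
#'
#' @param X Numeric matrix, samples x dimensions.
#' @param k Number of components (1 <= k <= n).
#' @param model \code{"diagonal"} (default) or \code{"spherical"}
#'   covariance family.
#' @param seed Integer seed.
#' @param nInit Number of restarts (default 5).
#' @param maxIter EM iteration cap (default 500).
#' @param tol Relative log-likelihood tolerance (default 1e-6).
#' @param varFloor Variance floor (default 1e-4).
#' @param keepTrace Attach the per-iteration log-likelihood trace of
#'   the winning restart as attribute \code{"trace"}.
#' @return A \linkS4class{GmmFit}.
#' @export
fitGmm <- function(X, k, model = c("diagonal", "spherical"),
                   seed = 1L, nInit = 5L, maxIter = 500L, tol = 1e-6,
                   varFloor = 1e-4, keepTrace = FALSE) {
  model <- match.arg(model)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (k < 1L || k > n) stop("need 1 <= k <= n")

  best <- NULL
  for (init in seq_len(nInit)) {
    set.seed(deriveSeed(seed, sprintf("gmm-k%d-init%d", k, init)))
    fit <- tryCatch(
      .emOnce(X, k, model, maxIter, tol, varFloor),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$logLik > best$logLik)) best <- fit
    if (k == 1L) break   # deterministic; restarts are identical
  }
  if (is.null(best)) stop("all EM restarts failed for k = ", k)

  p <- if (model == "diagonal") k * 2L * d + (k - 1L) else
    k * (d + 1L) + (k - 1L)
  out <- methods::new("GmmFit",
    k = as.integer(k), means = best$means, variances = best$variances,
    weights = as.numeric(best$weights), logLik = best$logLik,
    nParams = as.integer(p),
    bic = 2 * best$logLik - p * log(n),
    responsibilities = best$r,
    classification = as.integer(max.col(best$r)),
    model = model, converged = best$converged)
  if (keepTrace) attr(out, "trace") <- best$trace
  out
}

.emOnce <- function(X, k, model, maxIter, tol, varFloor) {
  n <- nrow(X); d <- ncol(X)
  centers <- .kmeansppCenters(X, k)
  ## hard-assign to centers to get starting parameters
  d2 <- vapply(seq_len(k), function(j) .sqDist(X, centers[j, ]),
               numeric(n))
  if (k == 1L) d2 <- matrix(d2, ncol = 1L)
  cl <- max.col(-d2)
  r <- matrix(0, n, k); r[cbind(seq_len(n), cl)] <- 1
  par <- .mstep(X, r + 1e-10, model, varFloor)

  ll <- -Inf; trace <- numeric(0); rescues <- 0L
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    ld <- .logDens(X, par$means, par$variances, par$weights)
    m <- apply(ld, 1, max)
    lse <- m + log(rowSums(exp(ld - m)))
    r <- exp(ld - lse)
    newll <- sum(lse)
    Nj <- colSums(r)
    if (any(Nj < 1e-8)) {
      if (rescues >= 3L) stop("EM component emptied repeatedly")
      rescues <- rescues + 1L
      dead <- which(Nj < 1e-8)
      for (j in dead) {
        far <- which.min(lse)        # worst-explained point
        par$means[j, ] <- X[far, ]
        par$variances[j, ] <- pmax(apply(X, 2, var) / k, varFloor)
        par$weights <- rep(1 / k, k)
      }
      ll <- -Inf
      next
    }
    par <- .mstep(X, r, model, varFloor)
    trace <- c(trace, newll)
    if (is.finite(ll) &&
        abs(newll - ll) < tol * (abs(newll) + .Machine$double.eps)) {
      ll <- newll
      converged <- TRUE
      break
    }
    ll <- newll
  }
  ## final E-step quantities consistent with returned parameters
  ld <- .logDens(X, par$means, par$variances, par$weights)
  m <- apply(ld, 1, max)
  lse <- m + log(rowSums(exp(ld - m)))
  r <- exp(ld - lse)
  list(means = par$means, variances = par$variances,
       weights = par$weights, logLik = sum(lse), r = r,
       converged = converged, trace = trace)
}

#' Choose the number of mixture components by BIC
#'
#' Fits \code{\link{fitGmm}} for every k in \code{kRange} and returns
#' the fit maximising BIC (\code{2 logL - p log n}); ties break toward
#' smaller k.
#'
#' @inheritParams fitGmm
#' @param kRange Integer vector of candidate component counts
#'   (default 1:9).
#' @return The winning \linkS4class{GmmFit}; the full BIC table is
#'   attached as attribute \code{"bicTable"}.
#' @export
selectK <- function(X, kRange = 1:9, model = c("diagonal", "spherical"),
                    seed = 1L, nInit = 5L, varFloor = 1e-4, ...) {
  model <- match.arg(model)
  X <- as.matrix(X)
  kRange <- sort(unique(as.integer(kRange)))
  kRange <- kRange[kRange >= 1L & kRange <= nrow(X)]
  if (!length(kRange)) stop("kRange is empty after bounds checks")
  fits <- vector("list", length(kRange))
  bics <- rep(NA_real_, length(kRange))
  for (i in seq_along(kRange)) {
    fits[[i]] <- tryCatch(
      fitGmm(X, kRange[i], model = model, seed = seed, nInit = nInit,
             varFloor = varFloor, ...),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) bics[i] <- fits[[i]]@bic
  }
  if (all(is.na(bics))) stop("every mixture fit failed")
  best <- which(bics == max(bics, na.rm = TRUE))[1L]  # ties: smaller k
  out <- fits[[best]]
  attr(out, "bicTable") <- data.frame(k = kRange, bic = bics)
  out
}
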