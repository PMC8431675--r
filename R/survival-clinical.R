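#' @importFrom survival Surv survfit
#' @importFrom MASS ginv
NULL

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator with Greenwood log-log 95 percent
#' confidence intervals. The median is the earliest time at which the
#' curve reaches 0.5 or below (undefined when never reached, as
#' happens under heavy censoring); the mean is reported as the
#' restricted mean, the area under the curve up to the largest
#' observed time.
#'
#' @param time Positive observation times.
#' @param event Event indicator (1 = deceased, 0 = censored).
#' @return A \linkS4class{KMCurve}.
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  sm <- summary(fit, rmean = max(time))
  ## earliest time at which the curve reaches 0.5 or below (survfit's
  ## table reports the midpoint when the curve sits exactly at 0.5)
  hit <- which(fit$surv <= 0.5 + 1e-12)
  med <- if (length(hit)) fit$time[min(hit)] else NA_real_
  methods::new("KMCurve",
    time = as.numeric(fit$time),
    survival = as.numeric(fit$surv),
    nRisk = as.integer(fit$n.risk),
    nEvent = as.integer(fit$n.event),
    nCensor = as.integer(fit$n.censor),
    lower = as.numeric(fit$lower),
    upper = as.numeric(fit$upper),
    median = if (is.na(med)) NA_real_ else as.numeric(med),
    restrictedMean = unname(sm$table["rmean"]),
    n = length(time))
}

#' Weighted log-rank family of k-sample survival tests
#'
#' At every distinct event time the observed-minus-expected event
#' vector and its hypergeometric covariance are accumulated with
#' weight w(t): 1 for the log-rank test, the number at risk for the
#' Breslow (Gehan generalised Wilcoxon) test, and its square root for
#' the Tarone-Ware test. The statistic is U' V^- U on the first
#' groups-1 coordinates with a chi-square reference on groups-1
#' degrees of freedom. Deaths precede censorings at tied times.
#'
#' @param time,event As in \code{\link{kmEstimate}}.
#' @param group Group labels (at least 2 groups).
#' @param scheme \code{"logrank"}, \code{"breslow"} or
#'   \code{"tarone_ware"}.
#' @return List with \code{chi2}, \code{df}, \code{p},
#'   \code{observed}, \code{expected} per group.
#' @export
weightedLogrank <- function(time, event,
                            group, scheme = c("logrank", "breslow",
                                              "tarone_ware")) {
  scheme <- match.arg(scheme)
  group <- as.character(group)
  groups <- sort(unique(group))
  K <- length(groups)
  if (K < 2L) stop("at least two groups are required")
  if (sum(event) == 0)
    return(list(chi2 = 0, df = K - 1L, p = 1,
                observed = setNames(rep(0, K), groups),
                expected = setNames(rep(0, K), groups)))
  eventTimes <- sort(unique(time[event == 1]))
  U <- rep(0, K); V <- matrix(0, K, K)
  O <- rep(0, K); E <- rep(0, K)
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    nG <- vapply(groups, function(g) sum(atRisk & group == g), 0)
    dG <- vapply(groups, function(g)
      sum(time == t & event == 1 & group == g), 0)
    d <- sum(dG)
    if (n <= 1 || d == 0) next
    w <- switch(scheme, logrank = 1, breslow = n,
                tarone_ware = sqrt(n))
    exp_ <- d * nG / n
    U <- U + w * (dG - exp_)
    O <- O + dG; E <- E + exp_
    frac <- nG / n
    cov <- (diag(frac, K) - outer(frac, frac)) *
      (d * (n - d) / max(n - 1, 1))
    V <- V + w^2 * cov
  }
  i <- seq_len(K - 1L)
  Vi <- V[i, i, drop = FALSE]
  chi2 <- as.numeric(t(U[i]) %*% MASS::ginv(Vi) %*% U[i])
  df <- K - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       observed = setNames(O, groups), expected = setNames(E, groups))
}

#' All pairwise two-group survival tests
#'
#' Runs every unordered subtype pair through the requested weighted
#' log-rank schemes and flags pairs with p below \code{alpha}.
#'
#' @inheritParams weightedLogrank
#' @param schemes Character vector of schemes (default all three).
#' @param alpha Flagging level (default 0.05).
#' @return data.frame with columns \code{group_a, group_b, scheme,
#'   chi2, p, unequal}.
#' @export
pairwiseSurvivalTests <- function(time, event, group,
                                  schemes = c("logrank", "breslow",
                                              "tarone_ware"),
                                  alpha = 0.05) {
  group <- as.character(group)
  groups <- sort(unique(group))
  if (length(groups) < 2L) stop("at least two groups are required")
  out <- list()
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (b <= a) next
    sel <- group %in% groups[c(a, b)]
    for (sc in schemes) {
      r <- weightedLogrank(time[sel], event[sel], group[sel], sc)
      out[[length(out) + 1L]] <- data.frame(
        group_a = groups[a], group_b = groups[b], scheme = sc,
        chi2 = r$chi2, p = r$p, unequal = r$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Subtype-by-sex and subtype-by-project frequency tables
#'
#' @param labels Named subtype labels.
#' @param clinical Clinical data.frame from \code{\link{readClinical}}.
#' @return List with \code{sex} and \code{project}, each containing
#'   \code{counts} and row-normalised \code{proportions}.
#' @export
clinicalFrequencies <- function(labels, clinical) {
  m <- match(names(labels), clinical$sample_id)
  sex <- clinical$sex[m]
  sex[is.na(sex)] <- "unknown"
  proj <- clinical$project_code[m]
  proj[is.na(proj)] <- "unknown"
  mk <- function(v) {
    counts <- table(subtype = labels, value = v)
    list(counts = counts,
         proportions = counts / rowSums(counts))
  }
  list(sex = mk(sex), project = mk(proj))
}

#' Assemble survival inputs for labelled samples
#'
#' Joins subtype labels with the clinical table, keeps
#' survival-eligible rows, and converts day-denominated times to
#' months (days / 30.44) when requested.
#'
#' @param labels Named subtype labels (outliers dropped).
#' @param clinical Clinical data.frame from \code{\link{readClinical}}.
#' @param toMonths Convert days to months (default TRUE).
#' @return data.frame with \code{sample_id, time, event, group}.
#' @export
survivalInput <- function(labels, clinical, toMonths = TRUE) {
  labels <- labels[labels != "OUTLIER"]
  m <- match(names(labels), clinical$sample_id)
  ok <- !is.na(m) & clinical$survival_eligible[m]
  df <- data.frame(
    sample_id = names(labels)[ok],
    time = clinical$survival_time[m[ok]],
    event = as.integer(clinical$vital_status[m[ok]] == "deceased"),
    group = unname(labels[ok]),
    stringsAsFactors = FALSE)
  if (toMonths) df$time <- df$time / 30.44
  df
}
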