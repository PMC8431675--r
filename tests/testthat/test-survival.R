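test_that("KM equals the empirical survival function without censoring", {
  km <- kmEstimate(1:4, rep(1, 4))
  expect_equal(km@survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km@median, 2)
  expect_equal(km@restrictedMean, 1 + 0.75 + 0.5 + 0.25)
  set.seed(5)
  tt <- sort(sample(1:100, 30))
  km2 <- kmEstimate(tt, rep(1, 30))
  emp <- vapply(km2@time, function(t) mean(tt > t), 0)
  expect_equal(km2@survival, emp)
})

test_that("KM handles censoring and the all-censored degenerate case", {
  ## deaths at 1 and 2, censoring at 1.5 (hand product-limit)
  km <- kmEstimate(c(1, 1.5, 2), c(1, 0, 1))
  expect_equal(km@survival, c(2 / 3, 2 / 3, 0))
  expect_equal(km@median, 2)
  ## all censored: flat curve, median undefined
  kc <- kmEstimate(c(3, 7, 9), c(0, 0, 0))
  expect_true(all(kc@survival == 1))
  expect_true(is.na(kc@median))
  expect_equal(kc@restrictedMean, 9)
  ## Greenwood bounds enclose the estimate
  st <- kmEstimate(rexp(50) + 0.1, rbinom(50, 1, 0.7))
  expect_true(all(st@lower <= st@survival + 1e-9, na.rm = TRUE))
  expect_true(all(st@upper >= st@survival - 1e-9, na.rm = TRUE))
})

test_that("identical groups give a null weighted log-rank statistic", {
  tt <- c(1, 3, 5, 7, 9); ev <- c(1, 1, 0, 1, 1)
  for (sc in c("logrank", "breslow", "tarone_ware")) {
    r <- weightedLogrank(c(tt, tt), c(ev, ev),
                         rep(c("a", "b"), each = 5), sc)
    expect_equal(r$chi2, 0, tolerance = 1e-12)
    expect_equal(r$p, 1)
  }
  expect_error(weightedLogrank(tt, ev, rep("a", 5)), "two groups")
  ## no events at all: p = 1 by convention
  r0 <- weightedLogrank(c(tt, tt), rep(0, 10),
                        rep(c("a", "b"), each = 5))
  expect_equal(r0$p, 1)
})

test_that("log-rank matches survival::survdiff and is label-invariant", {
  set.seed(7)
  tt <- c(rexp(40, 0.05), rexp(40, 0.15))
  ev <- rbinom(80, 1, 0.8)
  gr <- rep(c("a", "b"), each = 40)
  mine <- weightedLogrank(tt, ev, gr, "logrank")
  ref <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
  expect_equal(mine$chi2, ref$chisq, tolerance = 1e-9)
  ## relabeling the groups leaves the statistic unchanged
  swapped <- weightedLogrank(tt, ev, ifelse(gr == "a", "z", "y"),
                             "logrank")
  expect_equal(swapped$chi2, mine$chi2)
  ## shifting all times leaves every scheme unchanged
  for (sc in c("logrank", "breslow", "tarone_ware")) {
    a <- weightedLogrank(tt, ev, gr, sc)
    b <- weightedLogrank(tt + 100, ev, gr, sc)
    expect_equal(a$chi2, b$chi2, tolerance = 1e-9)
  }
})

test_that("weight schemes coincide when at-risk counts are constant", {
  ## a single death time: only one term in the sum, weights cancel in
  ## the quadratic form
  tt <- rep(5, 12); ev <- rep(1, 12)
  gr <- rep(c("a", "b"), 6)
  ps <- vapply(c("logrank", "breslow", "tarone_ware"), function(sc)
    weightedLogrank(tt, ev, gr, sc)$p, 0)
  expect_true(all(abs(ps - ps[1]) < 1e-12))
})

test_that("log-rank p agrees with a permutation oracle", {
  set.seed(11)
  tt <- c(rexp(15, 0.04), rexp(15, 0.15))
  ev <- rbinom(30, 1, 0.85)
  gr <- rep(c("a", "b"), each = 15)
  obs <- weightedLogrank(tt, ev, gr, "logrank")
  B <- 2000
  null <- vapply(seq_len(B), function(b) {
    weightedLogrank(tt, ev, sample(gr), "logrank")$chi2
  }, 0)
  pPerm <- (1 + sum(null >= obs$chi2)) / (B + 1)
  se <- sqrt(pPerm * (1 - pPerm) / B)
  expect_lt(abs(obs$p - pPerm), 4 * se + 0.01)
})

test_that("pairwise testing flags planted hazard differences", {
  flagged <- 0; nullFlags <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    tA <- rexp(100, 0.02); tB <- rexp(100, 0.10)
    cz <- rexp(200, 0.02)
    tt <- pmin(c(tA, tB), cz)
    ev <- as.integer(c(tA, tB) <= cz)
    gr <- rep(c("A", "B"), each = 100)
    r <- pairwiseSurvivalTests(tt, ev, gr)
    expect_identical(nrow(r), 3L)   # 1 pair x 3 schemes
    if (all(r$unequal)) flagged <- flagged + 1
    ## identical hazards: level check
    t0 <- rexp(200, 0.05); tt0 <- pmin(t0, cz)
    ev0 <- as.integer(t0 <= cz)
    r0 <- pairwiseSurvivalTests(tt0, ev0, gr, schemes = "logrank")
    if (any(r0$unequal)) nullFlags <- nullFlags + 1
  }
  expect_gte(flagged, 9)
  expect_lte(nullFlags, 3)
  ## K groups give K(K-1)/2 rows per scheme
  set.seed(2)
  tt <- rexp(40) + 0.1; gr4 <- rep(letters[1:4], 10)
  r4 <- pairwiseSurvivalTests(tt, rep(1, 40), gr4,
                              schemes = "logrank")
  expect_identical(nrow(r4), 6L)
})

test_that("estimated medians track the exponential truth", {
  for (s in 1:5) {
    set.seed(400 + s)
    hz <- 0.05
    tt <- rexp(250, hz)
    km <- kmEstimate(tt, rep(1, 250))
    expect_lt(abs(km@median - log(2) / hz) / (log(2) / hz), 0.15)
  }
})

test_that("clinical frequency tables recover planted compositions", {
  st <- smallStudy()
  cl <- readClinical(st$coh$clinical)
  labels <- truthLabels(st$coh)
  fr <- clinicalFrequencies(labels, cl)
  expect_equal(unname(rowSums(fr$sex$proportions)), rep(1, 3))
  expect_equal(unname(rowSums(fr$project$proportions)), rep(1, 3))
  expect_identical(sum(fr$sex$counts), length(labels))
  ## male fraction near the planted 0.57 (pooled over subtypes)
  maleFrac <- sum(fr$sex$counts[, "male"]) / length(labels)
  expect_lt(abs(maleFrac - 0.57), 0.15)
})

test_that("survival input assembly applies eligibility and units", {
  cl <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    sex = "male", project_code = "P",
    survival_time = c(304.4, 0, 100, NA),
    vital_status = c("deceased", "alive", "alive", "deceased"),
    stage = NA, grade = NA)
  cl <- readClinical(cl)
  labels <- setNames(c("S1", "S1", "S2", "OUTLIER"),
                     c("a", "b", "c", "d"))
  si <- survivalInput(labels, cl)
  expect_identical(si$sample_id, c("a", "c"))   # b: t=0, d: outlier
  expect_equal(si$time[1], 10)                  # days -> months
  expect_identical(si$event, c(1L, 0L))
})
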