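test_that("reclassification margins conserve the per-method distributions", {
  trad <- gradesFromCounts(c(16, 58, 13))
  semi <- gradesFromCounts(c(53, 26, 8))
  rt <- reclassification(trad, semi)
  expect_equal(unname(rowSums(counts(rt))), c(16, 58, 13))
  expect_equal(unname(colSums(counts(rt))), c(53, 26, 8))
  expect_equal(sum(counts(rt)), 87)

  same <- reclassification(c("G1", "G2", "G3"), c("G1", "G2", "G3"))
  expect_equal(unname(counts(same)), diag(c(1L, 1L, 1L)))
  expect_error(reclassification(character(0), character(0)), "empty")
})

test_that("chi-square matches brute-force O/E summation and stats::chisq.test", {
  O <- rbind(c(20, 5, 0), c(4, 30, 6), c(0, 3, 19))
  res <- chiSquare(O)
  # independent brute-force oracle, spelled out cell by cell
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  oracle <- 0
  for (i in 1:3) for (j in 1:3) oracle <- oracle + (O[i, j] - E[i, j])^2 / E[i, j]
  expect_equal(statistic(res), oracle, tolerance = 1e-12)
  expect_equal(res@df, 4)
  ref <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
  expect_equal(statistic(res), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pValue(res), unname(ref$p.value), tolerance = 1e-12)

  # identical row distributions => exact independence, statistic 0
  flat <- rbind(c(10, 20, 30), c(10, 20, 30), c(10, 20, 30))
  expect_equal(statistic(chiSquare(flat)), 0, tolerance = 1e-12)
})

test_that("chi-square equals the oracle on random tables with positive margins", {
  set.seed(99)
  reps <- 0
  while (reps < 500) {
    O <- matrix(rpois(9, 8), 3, 3)
    if (any(rowSums(O) == 0) || any(colSums(O) == 0)) next
    reps <- reps + 1
    ref <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
    expect_equal(statistic(chiSquare(O)), unname(ref$statistic),
                 tolerance = 1e-10)
  }
})

test_that("chi-square reports degenerate tables", {
  expect_error(chiSquare(rbind(c(5, 0, 0), c(3, 0, 0), c(2, 0, 0))),
               "degenerate")
})

test_that("pearsonCorr matches the defining formula and cor.test", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 7)
  # brute-force summation oracle
  r0 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearsonCorr(x, y)
  expect_equal(statistic(res), r0, tolerance = 1e-12)
  ref <- stats::cor.test(x, y)
  expect_equal(statistic(res), unname(ref$estimate), tolerance = 1e-12)
  expect_equal(pValue(res), ref$p.value, tolerance = 1e-12)

  expect_equal(statistic(pearsonCorr(x, x)), 1)
  expect_equal(statistic(pearsonCorr(x, -x)), -1)
  expect_error(pearsonCorr(x, rep(3, 5)), "zero variance")
  expect_error(pearsonCorr(1:2, 2:3), "at least 3")
})

test_that("pairedT matches the closed form and t.test", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)   # d = (1, 2, 3)
  res <- pairedT(x, y)
  expect_equal(statistic(res), 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res@df, 2)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(statistic(res), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pValue(res), ref$p.value, tolerance = 1e-12)

  same <- pairedT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(statistic(same), 0)
  expect_equal(pValue(same), 1)
  shifted <- pairedT(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(statistic(shifted)))
  expect_equal(pValue(shifted), 0)
  # df = n - 1 at cohort size
  set.seed(1)
  expect_equal(pairedT(rnorm(87), rnorm(87))@df, 86)
})

test_that("Kaplan-Meier matches the hand-applied product-limit formula", {
  tm <- c(1, 2, 2, 3, 4, 5); ev <- c(1, 1, 0, 1, 0, 1)
  cv <- kmEstimate(tm, ev)
  expect_equal(cv@times, c(1, 2, 3, 5))
  # hand product-limit: S(1)=5/6, S(2)=5/6*4/5, S(3)=...*2/3, S(5)=...*0
  expect_equal(cv@survival, c(5/6, 5/6 * 4/5, 5/6 * 4/5 * 2/3, 0),
               tolerance = 1e-12)
  expect_equal(cv@atRisk, c(6L, 5L, 3L, 1L))

  none <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(length(none@times), 0)

  single <- kmEstimate(1, TRUE)
  expect_equal(single@survival, 0)
  expect_error(kmEstimate(-1, TRUE), ">= 0")
})

test_that("Kaplan-Meier agrees with survival::survfit on permuted fixtures", {
  skip_if_not_installed("survival")
  tm <- c(1, 2, 2, 3, 4, 5); ev <- c(1, 1, 0, 1, 0, 1)
  set.seed(3)
  for (i in 1:20) {
    p <- sample(6)
    cv <- kmEstimate(tm[p], ev[p])
    sf <- survival::survfit(survival::Surv(tm[p], ev[p]) ~ 1)
    ref <- summary(sf, times = cv@times)
    expect_equal(cv@survival, ref$surv, tolerance = 1e-12)
  }
})

test_that("log-rank matches the hand O/E/V table and survival::survdiff", {
  # all of group A dies at t=1, all of B at t=10: single informative time,
  # O-E = 5 - 5*5/10 = 2.5, V = 5*(1/4)*(5/9), statistic = 2.5^2/V = 9
  res <- logRank(rep(1, 5), rep(TRUE, 5), rep(10, 5), rep(TRUE, 5))
  expect_equal(statistic(res), 9, tolerance = 1e-12)
  expect_equal(res@df, 1)

  skip_if_not_installed("survival")
  set.seed(8)
  for (i in 1:20) {
    tA <- sample(1:8, 5, replace = TRUE); eA <- runif(5) < 0.7
    tB <- sample(1:8, 5, replace = TRUE); eB <- runif(5) < 0.7
    if (!any(eA) && !any(eB)) next
    res <- logRank(tA, eA, tB, eB)
    sd <- survival::survdiff(
      survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(1:2, each = 5))
    expect_equal(statistic(res), unname(sd$chisq), tolerance = 1e-10)
  }
})

test_that("log-rank is symmetric in group labels and null on identical groups", {
  tA <- c(1, 3, 5, 7); eA <- c(1, 0, 1, 1)
  same <- logRank(tA, eA, tA, eA)
  expect_equal(statistic(same), 0, tolerance = 1e-12)
  expect_equal(pValue(same), 1, tolerance = 1e-12)

  tB <- c(2, 4, 6, 8); eB <- c(1, 1, 0, 1)
  ab <- logRank(tA, eA, tB, eB)
  ba <- logRank(tB, eB, tA, eA)
  expect_equal(statistic(ab), statistic(ba), tolerance = 1e-12)

  expect_error(logRank(1:3, rep(FALSE, 3), 4:6, rep(FALSE, 3)), "no events")
  expect_error(logRank(numeric(0), logical(0), 1, TRUE), "non-empty")
})

test_that("dichotomize applies the grade boundary and median rules", {
  df <- data.frame(traditional_index = c(2.9, 3.0, 10, 1),
                   semiquantal_index = c(1, 2, 4, 5),
                   mitotic_count = c(0, 1, 2, 30))
  gt <- dichotomize(df, "grade_threshold", "traditional")
  expect_equal(gt$high, c(FALSE, TRUE, TRUE, FALSE))

  md <- dichotomize(df, "median", "semiquantal")
  expect_equal(md$high, c(FALSE, FALSE, TRUE, TRUE))   # median 3, ties low

  mit <- dichotomize(df, "grade_threshold", "mitoses")
  expect_equal(mit$high, c(FALSE, FALSE, TRUE, TRUE))

  zero <- data.frame(traditional_index = rep(0, 4),
                     semiquantal_index = rep(0, 4),
                     mitotic_count = rep(0, 4))
  expect_warning(out <- dichotomize(zero, "grade_threshold", "traditional"),
                 "degenerate")
  expect_true(out$degenerate)
})

test_that("cohortComparison assembles a coherent report", {
  coh <- simulateCohort(cohortSimParams(seed = 17L))
  rep <- cohortComparison(coh)
  expect_s4_class(rep$reclassification, "ReclassTable")
  expect_equal(sum(counts(rep$reclassification)), nrow(coh))
  expect_s4_class(rep$pairedT, "StatResult")
  expect_gt(statistic(rep$pairedT), 0)  # traditional exceeds semiquantal
  expect_s4_class(rep$correlations$traditional_semiquantal, "StatResult")
  expect_true(all(c("traditional", "semiquantal", "mitoses") %in%
                  names(rep$survival)))
  sv <- rep$survival$semiquantal
  expect_s4_class(sv$high, "SurvivalCurve")
  expect_equal(sv$nHigh + sv$nLow, nrow(coh))
})
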