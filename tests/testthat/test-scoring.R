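test_that("intensity classes respect thresholds with upper-class boundaries", {
  cls <- classifyIntensity(c(0, 0.149, 0.15, 0.30, 0.599, 0.60, 1.2))
  expect_equal(as.character(cls),
               c("negative", "negative", "low", "low", "low", "high", "high"))
  rec <- data.frame(meanDabOD = 0.3, included = FALSE)
  expect_error(classifyIntensity(rec), "excluded")
})

test_that("scoreField counts only included records and partitions the total", {
  expect_equal(unname(counts(scoreField(NULL))), c(0L, 0L, 0L, 0L))

  rec <- data.frame(
    meanDabOD = c(rep(0.01, 85), rep(0.3, 10), rep(0.9, 5), 0.9),
    included = c(rep(TRUE, 100), FALSE),
    stringsAsFactors = FALSE)
  fs <- scoreField(rec)
  cnt <- counts(fs)
  expect_equal(unname(cnt), c(100L, 85L, 10L, 5L))
  expect_equal(cnt[["negative"]] + cnt[["low"]] + cnt[["high"]],
               cnt[["total"]])
})

test_that("case pooling computes both indices and flags thin material", {
  flds <- replicate(10, fsCounts(100, 10, 5), simplify = FALSE)
  cs <- scoreCase(flds, mitoticCount = 2L)
  expect_equal(traditionalIndex(cs), 15.0)
  expect_equal(semiquantalIndex(cs), 5.0)
  expect_true(isValid(cs))

  allNeg <- replicate(10, fsCounts(50, 0, 0), simplify = FALSE)
  cs0 <- scoreCase(allNeg, 0L)
  expect_equal(traditionalIndex(cs0), 0)
  expect_equal(semiquantalIndex(cs0), 0)

  nine <- replicate(9, fsCounts(100, 10, 5), simplify = FALSE)
  cs9 <- scoreCase(nine, 0L)
  expect_false(isValid(cs9))
  expect_match(paste(cs9@validityNotes, collapse = " "), "field")

  few <- list(fsCounts(50, 5, 2))
  csf <- scoreCase(few, 0L)
  expect_false(isValid(csf))
  expect_match(paste(csf@validityNotes, collapse = " "), "nuclei")

  expect_error(scoreCase(list(fsCounts(0, 0, 0)), 0L), "empty case")
  expect_error(scoreCase(flds, -1L), "non-negative")
})

test_that("pooled index is a cellularity-weighted mean, order-invariant", {
  flds <- list(fsCounts(200, 40, 10), fsCounts(50, 0, 0),
               fsCounts(120, 12, 24), fsCounts(80, 8, 0))
  cs <- scoreCase(flds, 0L, minFields = 1L)
  w <- c(200, 50, 120, 80)
  fTrad <- c(50 / 200, 0, 36 / 120, 8 / 80) * 100
  expect_equal(traditionalIndex(cs), sum(w * fTrad) / sum(w))
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    csP <- scoreCase(flds[perm], 0L, minFields = 1L)
    expect_equal(traditionalIndex(csP), traditionalIndex(cs))
    expect_equal(semiquantalIndex(csP), semiquantalIndex(cs))
  }
})

test_that("semiquantal index never exceeds traditional on random fields", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(50:300, 1)
    lo <- rbinom(1, n, 0.2); hi <- rbinom(1, n - lo, 0.3)
    cs <- scoreCase(list(fsCounts(n, lo, hi)), 0L, minFields = 1L)
    expect_lte(semiquantalIndex(cs), traditionalIndex(cs))
  }
})

test_that("Ki-67 grade thresholds follow the WHO bands", {
  expect_equal(as.character(gradeFromKi67(c(0, 2, 2.99, 3, 20))),
               c("G1", "G1", "G1", "G2", "G2"))
  expect_equal(as.character(gradeFromKi67(c(20.01, 100))), c("G3", "G3"))
  expect_error(gradeFromKi67(-1), "\\[0, 100\\]")
  expect_error(gradeFromKi67(101), "\\[0, 100\\]")
  # monotone non-decreasing in the index
  g <- as.integer(gradeFromKi67(seq(0, 100, by = 0.5)))
  expect_true(all(diff(g) >= 0))
})

test_that("mitotic grade thresholds follow the WHO bands", {
  expect_equal(as.character(gradeFromMitoses(c(0, 1, 2, 20, 21, 113))),
               c("G1", "G1", "G2", "G2", "G3", "G3"))
  expect_error(gradeFromMitoses(-1), ">= 0")
})

test_that("combined grade takes the worse component", {
  expect_equal(grade(combinedGrade(1.0, 25L)), "G3")   # mitoses dominate
  expect_equal(grade(combinedGrade(25.0, 0L)), "G3")   # index dominates
  expect_equal(grade(combinedGrade(1.0, 1L)), "G1")
  g <- combinedGrade(c(1, 5, 30), c(25, 1, 0))
  expect_equal(as.character(g$grade), c("G3", "G2", "G3"))
  # monotone in both arguments
  expect_true(all(as.integer(combinedGrade(c(1, 5, 25), rep(0, 3))$grade) ==
                  cummax(as.integer(combinedGrade(c(1, 5, 25), rep(0, 3))$grade))))
})

test_that("for a fixed mitotic count the semiquantal grade never exceeds the traditional", {
  set.seed(7)
  trad <- runif(200, 0, 60)
  semi <- trad * runif(200)
  for (mc in c(0L, 5L, 25L)) {
    gt <- combinedGrade(trad, rep(mc, 200))$grade
    gs <- combinedGrade(semi, rep(mc, 200))$grade
    expect_true(all(as.integer(gs) <= as.integer(gt)))
  }
})

test_that("gradeCase grades both methods of one CaseScore", {
  flds <- replicate(10, fsCounts(100, 15, 2), simplify = FALSE)
  cs <- scoreCase(flds, 1L)
  gr <- gradeCase(cs)
  expect_equal(grade(gr$traditional), "G2")   # 17% stained
  expect_equal(grade(gr$semiquantal), "G1")   # 2% high
})
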