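# Render k well-separated disks and return the ODImage plus truth.
renderDisks <- function(k, seed = 1L, radiusUm = c(4, 4), width = 420L) {
  p <- fieldSimParams(nTumorNuclei = as.integer(k), nucleusRadiusUm = radiusUm,
                      widthPx = width, heightPx = width,
                      classProportions = c(0.5, 0.3, 0.2),
                      noiseSD = 0, seed = as.integer(seed))
  rf <- renderField(p)
  list(od = fieldToOD(rf$field), truth = rf$truth)
}

test_that("blank and all-zero fields segment to an empty mask", {
  blank <- renderField(fieldSimParams(nTumorNuclei = 0L, widthPx = 100L,
                                      heightPx = 100L, seed = 1L))
  mask <- segmentNuclei(fieldToOD(blank$field))
  expect_true(all(mask == 0L))

  zero <- new("ODImage", hema = matrix(0, 50, 50), dab = matrix(0, 50, 50),
              residual = matrix(0, 50, 50), mpp = 0.5)
  expect_true(all(segmentNuclei(zero) == 0L))
})

test_that("well-separated disks are each found once with accurate centroids", {
  for (k in c(1L, 10L, 50L)) {
    rd <- renderDisks(k, seed = 20L + k)
    mask <- segmentNuclei(rd$od)
    expect_equal(max(mask), k)
    rec <- extractRecords(mask, rd$od)
    expect_equal(nrow(rec), k)
    # match each truth centroid to the nearest record
    for (i in seq_len(k)) {
      d2 <- (rec$row - rd$truth$nuclei$row[i])^2 +
            (rec$col - rd$truth$nuclei$col[i])^2
      expect_lt(min(d2), 1.0^2 + 1e-9)
    }
  }
})

test_that("segmentation count matches ground truth for k in {0,1,10,100}", {
  counts <- vapply(c(0L, 1L, 10L, 100L), function(k) {
    rd <- renderDisks(k, seed = 31L + k, width = 500L)
    max(segmentNuclei(rd$od))
  }, numeric(1))
  expect_equal(counts, c(0, 1, 10, 100))
})

test_that("two moderately overlapping disks are split by the watershed", {
  # hand-built fixture: two disks of radius 8 px whose centres sit 1.7 r
  # apart (overlapping by ~30% of a radius)
  h <- w <- 80
  hema <- matrix(0, h, w); dab <- matrix(0, h, w)
  for (ctr in list(c(40, 33), c(40, 33 + 13.6))) {
    dy <- outer(seq_len(h) - ctr[1], rep(1, w))
    dx <- outer(rep(1, h), seq_len(w) - ctr[2])
    inside <- dy^2 + dx^2 <= 8^2
    hema[inside] <- 0.45; dab[inside] <- 0.35
  }
  od <- deconvolve(rgbToOD(composeOD(hema, dab)), mpp = 0.5)
  mask <- segmentNuclei(od)
  expect_equal(max(mask), 2)
})

test_that("record pixel counts partition the foreground", {
  rd <- renderDisks(30L, seed = 77L)
  mask <- segmentNuclei(rd$od)
  rec <- extractRecords(mask, rd$od)
  expect_equal(sum(round(rec$areaUm2 / mpp(rd$od)^2)), sum(mask > 0))
  expect_false(any(duplicated(rec$label)))
})

test_that("inclusion filters catch small, large and spindle-shaped objects", {
  mppv <- 0.5
  h <- w <- 120
  hema <- matrix(0, h, w); dab <- matrix(0, h, w); mask <- matrix(0L, h, w)
  mk <- function(cy, cx, a, b) {
    dy <- outer(seq_len(h) - cy, rep(1, w))
    dx <- outer(rep(1, h), seq_len(w) - cx)
    (dy / a)^2 + (dx / b)^2 <= 1
  }
  # labels applied directly so each object is a single region
  small <- mk(20, 20, 3.57, 3.57)       # area ~10 um^2
  spindle <- mk(60, 60, 30, 5)          # 6:1 axis ratio, valid area
  huge <- mk(60, 100, 42, 15)           # area ~ 495 um^2
  good <- mk(100, 25, 7.14, 7.14)       # area ~40 um^2
  mask[small] <- 1L; mask[spindle] <- 2L; mask[huge] <- 3L; mask[good] <- 4L
  hema[mask > 0] <- 0.45
  dab[good] <- 0.8
  od <- deconvolve(rgbToOD(composeOD(hema, dab)), mpp = mppv)
  rec <- extractRecords(mask, od)
  rec <- rec[order(rec$label), ]
  expect_equal(rec$exclusionReason, c("too_small", "spindle", "too_large",
                                      "none"))
  expect_gt(rec$eccentricity[2], 0.95)
  expect_true(rec$included[4])
  expect_lt(abs(rec$meanDabOD[4] - 0.8), 0.05)
  expect_lt(abs(rec$areaUm2[4] - 40), 8)

  # the same good disk found by the full segmentation keeps its properties
  segRec <- extractRecords(segmentNuclei(od), od)
  near <- which.min((segRec$row - 100)^2 + (segRec$col - 25)^2)
  expect_true(segRec$included[near])
  expect_lt(abs(segRec$meanDabOD[near] - 0.8), 0.05)
})

test_that("eccentricity follows sqrt(1 - (b/a)^2) for rendered ellipses", {
  h <- w <- 100
  hema <- matrix(0, h, w)
  dy <- outer(seq_len(h) - 50, rep(1, w))
  dx <- outer(rep(1, h), seq_len(w) - 50)
  hema[(dy / 36)^2 + (dx / 6)^2 <= 1] <- 0.5
  od <- deconvolve(rgbToOD(composeOD(hema, matrix(0, h, w))), mpp = 0.5)
  mask <- matrix(as.integer(hemaOD(od) > 0.2), h, w)
  rec <- extractRecords(mask, od)
  expect_equal(rec$eccentricity, sqrt(1 - (6 / 36)^2), tolerance = 0.01)
})

test_that("shrinking the area floor never loses included records", {
  rd <- renderDisks(40L, seed = 5L, radiusUm = c(2.2, 5))
  mask <- segmentNuclei(rd$od)
  floors <- c(40, 30, 20, 10, 1)
  nInc <- vapply(floors, function(f)
    sum(extractRecords(mask, rd$od, segParams(minAreaUm2 = f))$included),
    numeric(1))
  expect_true(all(diff(nInc) >= 0))
})

test_that("extractRecords validates shapes", {
  rd <- renderDisks(3L, seed = 2L, width = 150L)
  expect_error(extractRecords(matrix(0L, 10, 10), rd$od), "shape")
})
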