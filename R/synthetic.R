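#' @describeIn renderField construct and validate generator settings; see
#'   [FieldSimParams] for the meaning and defaults of every slot.
#' @param ... slots of [FieldSimParams] to override.
#' @export
fieldSimParams <- function(...) {
  args <- list(...)
  int <- c("widthPx", "heightPx", "nTumorNuclei", "nStromal", "i0", "seed")
  for (nm in intersect(names(args), int)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "FieldSimParams"), args))
}

# Named sub-streams: every stochastic stage draws from its own seed derived
# from the single field/cohort seed, so adding draws to one stage cannot
# perturb another.
.subSeed <- function(seed, stream) {
  offs <- c(class = 1L, placement = 2L, intensity = 3L, noise = 4L,
            cohortGrade = 5L, cohortIndex = 6L, cohortMitoses = 7L,
            cohortSurvival = 8L, cohortCovariates = 9L)
  as.integer((as.numeric(seed) * 7919 + offs[[stream]] * 104729) %% 2147483629)
}

# Rasterize an ellipse (semi-axes a >= b in px, orientation theta) into
# TRUE pixel indices of an H x W canvas, returned as an index vector.
.ellipsePixels <- function(cy, cx, a, b, theta, h, w) {
  rr <- max(a, b)
  r0 <- max(1L, floor(cy - rr)); r1 <- min(h, ceiling(cy + rr))
  c0 <- max(1L, floor(cx - rr)); c1 <- min(w, ceiling(cx + rr))
  ys <- r0:r1; xs <- c0:c1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ij <- which(inside, arr.ind = TRUE)
  if (!nrow(ij)) return(integer(0))
  (c0 + ij[, 2] - 1L - 1L) * h + (r0 + ij[, 1] - 1L)
}

#' Render a synthetic H-DAB field with per-nucleus ground truth
#'
#' Places non-overlapping tumour nuclei (near-circular disks with
#' class-conditional DAB optical density and a shared hematoxylin
#' counterstain) and optional spindle-shaped stromal confounders on a blank
#' canvas, renders them to 8-bit RGB through [composeOD()], and adds
#' Gaussian pixel noise. Deterministic given the seed.
#'
#' @param params a [FieldSimParams] object.
#' @return list with `field` (an [RGBField]), and `truth`: a data.frame of
#'   per-nucleus ground truth (`row`, `col`, `a`, `b`, `theta` in pixels /
#'   radians, `class`, `dabOD`, `hemaOD`) plus `traditionalIndex` /
#'   `semiquantalIndex` computed from the tumour-nucleus class labels only
#'   (stromal nuclei are false positives and never enter the truth), and
#'   `indicesDefined` (FALSE for a field without tumour nuclei).
#' @examples
#' rf <- renderField(fieldSimParams(nTumorNuclei = 10L, widthPx = 150L,
#'                                  heightPx = 150L, seed = 7L))
#' rf$truth$traditionalIndex
#' @export
renderField <- function(params = fieldSimParams()) {
  stopifnot(is(params, "FieldSimParams"))
  validObject(params)
  h <- params@heightPx; w <- params@widthPx
  nT <- params@nTumorNuclei; nS <- params@nStromal
  n <- nT + nS

  # class stream: tumour intensity classes
  set.seed(.subSeed(params@seed, "class"))
  classes <- if (nT > 0)
    sample(c("negative", "low", "high"), nT, replace = TRUE,
           prob = params@classProportions)
  else character(0)

  # placement stream: sizes, orientations, rejection-sampled centres
  set.seed(.subSeed(params@seed, "placement"))
  aPx <- bPx <- theta <- numeric(n)
  if (nT > 0) {
    rUm <- stats::runif(nT, params@nucleusRadiusUm[1],
                        params@nucleusRadiusUm[2])
    aPx[seq_len(nT)] <- bPx[seq_len(nT)] <- rUm / params@mpp
    theta[seq_len(nT)] <- 0
  }
  if (nS > 0) {
    bS <- params@stromalMinorAxisUm / params@mpp
    idx <- nT + seq_len(nS)
    bPx[idx] <- bS
    aPx[idx] <- bS * params@stromalAxisRatio
    theta[idx] <- stats::runif(nS, 0, pi)
  }
  cy <- cx <- numeric(n)
  rEff <- pmax(aPx, bPx)
  margin <- 1
  shrink <- 1 - params@maxOverlapFraction
  maxAttempts <- 500L
  for (i in seq_len(n)) {
    lo <- rEff[i] + 2; hiY <- h - rEff[i] - 1; hiX <- w - rEff[i] - 1
    if (hiY <= lo || hiX <= lo)
      stop(sprintf("packing failure: nucleus %d does not fit the canvas; placed %d of %d",
                   i, i - 1L, n))
    ok <- FALSE
    for (att in seq_len(maxAttempts)) {
      y <- stats::runif(1, lo, hiY); x <- stats::runif(1, lo, hiX)
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        minD <- shrink * (rEff[i] + rEff[j]) + margin
        ok <- all((cy[j] - y)^2 + (cx[j] - x)^2 >= minD^2)
      }
      if (ok) { cy[i] <- y; cx[i] <- x; break }
    }
    if (!ok)
      stop(sprintf("packing failure: placed %d of %d nuclei; reduce counts or canvas density",
                   i - 1L, n))
  }

  # intensity stream: per-nucleus optical densities
  set.seed(.subSeed(params@seed, "intensity"))
  classMean <- stats::setNames(params@dabODByClass,
                               c("negative", "low", "high"))
  dab <- c(if (nT > 0) pmax(0, stats::rnorm(nT, classMean[classes],
                                            params@dabODJitterSD)),
           rep(params@stromalDabOD, nS))
  hema <- pmax(0, stats::rnorm(n, params@hemaODMean, params@hemaODJitterSD))

  hemaMap <- matrix(0, h, w); dabMap <- matrix(0, h, w)
  for (i in seq_len(n)) {
    px <- .ellipsePixels(cy[i], cx[i], aPx[i], bPx[i], theta[i], h, w)
    hemaMap[px] <- pmax(hemaMap[px], hema[i])
    dabMap[px] <- pmax(dabMap[px], dab[i])
  }
  pixels <- composeOD(hemaMap, dabMap, i0 = params@i0)

  # noise stream: additive Gaussian pixel noise
  if (params@noiseSD > 0) {
    set.seed(.subSeed(params@seed, "noise"))
    pixels <- round(pixels + stats::rnorm(length(pixels),
                                          sd = params@noiseSD))
    pixels[pixels < 0] <- 0
    pixels[pixels > 255] <- 255
  }

  cls <- c(classes, rep("stromal", nS))
  truth <- list(
    nuclei = data.frame(row = cy, col = cx, a = aPx, b = bPx, theta = theta,
                        class = cls, dabOD = dab, hemaOD = hema,
                        stringsAsFactors = FALSE),
    indicesDefined = nT > 0,
    traditionalIndex = if (nT > 0)
      100 * mean(classes %in% c("low", "high")) else NA_real_,
    semiquantalIndex = if (nT > 0)
      100 * mean(classes == "high") else NA_real_)
  list(field = rgbField(pixels, mpp = params@mpp,
                        fieldId = sprintf("sim-%d", params@seed)),
       truth = truth)
}

#' @describeIn simulateCohort construct and validate generator settings;
#'   see [CohortSimParams] for the meaning and defaults of every slot.
#' @param ... slots of [CohortSimParams] to override.
#' @export
cohortSimParams <- function(...) {
  args <- list(...)
  for (nm in intersect(names(args), c("nPatients", "seed")))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "CohortSimParams"), args))
}

# Grade-consistent index bands used to clip the grade-conditional draws.
.gradeBands <- rbind(G1 = c(0, 2.99), G2 = c(3, 20), G3 = c(20.01, 100))

#' Simulate a GEP-NET patient cohort
#'
#' Per patient: a latent grade from the mixture; a semiquantal Ki-67 index
#' from the grade's log-normal, clipped into the grade-consistent band; a
#' traditional index equal to the semiquantal index plus a non-negative
#' log-normal low-stain excess (capped at 100); a mitotic count from
#' `Poisson(mitosisRate * semiquantal)`; overall survival exponential with
#' the latent grade's hazard under uniform administrative censoring; age,
#' sex, location and disease-free interval as independent covariates.
#' Recorded WHO grades are recomputed from the generated indices and
#' mitotic counts via [combinedGrade()]. Deterministic given the seed.
#'
#' @param params a [CohortSimParams] object.
#' @return cohort data.frame with columns `case_id`, `age_years`, `sex`,
#'   `location`, `dfi_years`, `os_years`, `event`, `traditional_index`,
#'   `semiquantal_index`, `mitotic_count`, `grade_traditional`,
#'   `grade_semiquantal`, and the `latent_grade` driving the hazard.
#' @examples
#' coh <- simulateCohort(cohortSimParams(nPatients = 20L, seed = 3L))
#' all(coh$semiquantal_index <= coh$traditional_index)
#' @export
simulateCohort <- function(params = cohortSimParams()) {
  stopifnot(is(params, "CohortSimParams"))
  validObject(params)
  n <- params@nPatients

  set.seed(.subSeed(params@seed, "cohortGrade"))
  g <- sample(1:3, n, replace = TRUE, prob = params@gradeMixture)

  set.seed(.subSeed(params@seed, "cohortIndex"))
  semi <- stats::rlnorm(n, params@indexMeanlog[g], params@indexSdlog[g])
  semi <- pmin(pmax(semi, .gradeBands[g, 1]), .gradeBands[g, 2])
  excess <- stats::rlnorm(n, params@excessMeanlog, params@excessSdlog)
  trad <- pmin(semi + excess, 100)

  set.seed(.subSeed(params@seed, "cohortMitoses"))
  mc <- stats::rpois(n, params@mitosisRate * semi)

  set.seed(.subSeed(params@seed, "cohortSurvival"))
  tEvent <- stats::rexp(n, rate = params@hazardByGrade[g])
  censor <- stats::runif(n, params@followupRangeYears[1],
                         params@followupRangeYears[2])
  os <- pmin(tEvent, censor)
  event <- tEvent <= censor

  set.seed(.subSeed(params@seed, "cohortCovariates"))
  age <- pmax(18, stats::rnorm(n, params@ageMeanYears, params@ageSdYears))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  loc <- ifelse(stats::runif(n) < params@pancreaticFraction,
                "pancreatic", "non_pancreatic")
  dfi <- stats::rlnorm(n, params@dfiMeanlog, params@dfiSdlog)

  gt <- combinedGrade(trad, mc)
  gs <- combinedGrade(semi, mc)
  if (n == 1L) {
    gt <- data.frame(grade = gt@grade)
    gs <- data.frame(grade = gs@grade)
  }
  data.frame(case_id = sprintf("case-%03d", seq_len(n)),
             age_years = age, sex = sex, location = loc,
             dfi_years = dfi, os_years = os, event = event,
             traditional_index = trad, semiquantal_index = semi,
             mitotic_count = mc,
             grade_traditional = as.character(gt$grade),
             grade_semiquantal = as.character(gs$grade),
             latent_grade = GRADE_LEVELS[g],
             stringsAsFactors = FALSE)
}

#' Write a fixed fixture suite to disk
#'
#' Renders a standard battery of fields (blank, sparse, dense,
#' stromal-heavy, boundary-intensity) as PNG images with sidecar ground
#' truth JSON, one simulated cohort CSV, and a manifest recording every
#' file's seed, parameters and MD5 hash. Rerunning with the same seed
#' produces identical hashes.
#'
#' @param outdir writable output directory (created if needed).
#' @param seed integer seed driving every fixture.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
makeTestSuite <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  specs <- list(
    blank = fieldSimParams(nTumorNuclei = 0L, nStromal = 0L, seed = seed),
    sparse = fieldSimParams(nTumorNuclei = 30L, seed = seed + 1L),
    dense = fieldSimParams(nTumorNuclei = 150L, widthPx = 500L,
                           heightPx = 500L, seed = seed + 2L),
    stromal = fieldSimParams(nTumorNuclei = 100L, nStromal = 50L,
                             widthPx = 500L, heightPx = 500L,
                             seed = seed + 3L),
    boundary = fieldSimParams(nTumorNuclei = 40L,
                              classProportions = c(0.5, 0.25, 0.25),
                              dabODByClass = c(0.02, 0.35, 0.60),
                              dabODJitterSD = 0, noiseSD = 0,
                              seed = seed + 4L))
  entries <- list()
  for (nm in names(specs)) {
    rf <- renderField(specs[[nm]])
    png <- file.path(outdir, paste0(nm, ".png"))
    writeFieldImage(rf$field, png)
    sidecar <- file.path(outdir, paste0(nm, ".json"))
    jsonlite::write_json(
      list(mpp = mpp(rf$field), seed = specs[[nm]]@seed,
           n_nuclei = nrow(rf$truth$nuclei),
           traditional_index = rf$truth$traditionalIndex,
           semiquantal_index = rf$truth$semiquantalIndex,
           nuclei = rf$truth$nuclei),
      sidecar, auto_unbox = TRUE, digits = NA, na = "null")
    entries[[nm]] <- list(
      image = basename(png), sidecar = basename(sidecar),
      seed = specs[[nm]]@seed, n_nuclei = nrow(rf$truth$nuclei),
      md5_image = unname(tools::md5sum(png)),
      md5_sidecar = unname(tools::md5sum(sidecar)))
  }
  coh <- simulateCohort(cohortSimParams(seed = seed + 5L))
  csv <- file.path(outdir, "cohort.csv")
  utils::write.csv(coh, csv, row.names = FALSE)
  manifest <- list(seed = seed, fields = entries,
                   cohort = list(file = basename(csv),
                                 seed = seed + 5L, n = nrow(coh),
                                 md5 = unname(tools::md5sum(csv))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
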