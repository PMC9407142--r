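#' Construct segmentation parameters
#'
#' @param minAreaUm2,maxAreaUm2 nucleus area acceptance window in um^2.
#' @param maxEccentricity spindle filter: inclusion requires eccentricity
#'   strictly below this value.
#' @param smoothingSigmaUm Gaussian smoothing sigma in um.
#' @param minPeakSeparationUm minimum marker separation in um.
#' @param minNuclearOD noise floor for the nuclear-OD threshold.
#' @return a validated [SegParams] object.
#' @examples
#' segParams(minAreaUm2 = 15)
#' @export
segParams <- function(minAreaUm2 = 20, maxAreaUm2 = 400,
                      maxEccentricity = 0.95, smoothingSigmaUm = 0.5,
                      minPeakSeparationUm = 3, minNuclearOD = 0.1) {
  new("SegParams", minAreaUm2 = minAreaUm2, maxAreaUm2 = maxAreaUm2,
      maxEccentricity = maxEccentricity, smoothingSigmaUm = smoothingSigmaUm,
      minPeakSeparationUm = minPeakSeparationUm, minNuclearOD = minNuclearOD)
}

#' Construct intensity classification thresholds
#'
#' @param tNeg,tHigh DAB optical-density boundaries, 0 < tNeg < tHigh. A
#'   mean nuclear DAB OD at a boundary belongs to the upper class.
#' @return a validated [IntensityThresholds] object.
#' @export
intensityThresholds <- function(tNeg = 0.15, tHigh = 0.60) {
  new("IntensityThresholds", tNeg = tNeg, tHigh = tHigh)
}

# Deterministic local maxima of a distance map: candidates are pixels equal
# to the grayscale dilation of the map within a disc of radius sep; they are
# visited in lexicographic (row, col) order and greedily accepted when at
# least sep away from every accepted peak.
.localMaxima <- function(dist, sep, fg) {
  b <- 2L * as.integer(floor(sep)) + 1L
  if (b < 3L) b <- 3L
  dil <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(dist), EBImage::makeBrush(b, "disc")))
  cand <- which(fg & dist >= dil - 1e-9)
  if (!length(cand)) return(matrix(numeric(0), 0, 2))
  ij <- arrayInd(cand, dim(dist))
  ord <- order(ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  sep2 <- sep^2
  for (k in seq_len(nrow(ij))) {
    p <- ij[k, ]
    if (!nrow(keep) ||
        min((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2) >= sep2)
      keep <- rbind(keep, p)
  }
  keep
}

#' Segment nuclei from optical-density maps
#'
#' Marker-controlled watershed on the total nuclear optical density
#' (hematoxylin + DAB): Gaussian smoothing, Otsu threshold on the
#' square-root-compressed map (so pale and dark nuclei are detected alike
#' and the cut separates tissue from background; never taken below the
#' `minNuclearOD` noise floor), hole filling, Euclidean distance
#' transform, local maxima as markers (minimum separation
#' `minPeakSeparationUm`, ties broken in lexicographic (row, col) order),
#' then watershed by geodesic propagation on the inverted distance map.
#' The procedure is fully deterministic.
#'
#' @param od an [ODImage].
#' @param params a [SegParams] object; geometric settings are in um and are
#'   converted through the image's mpp.
#' @return integer H x W label matrix; 0 is background. A blank or all-zero
#'   field yields an all-zero mask.
#' @export
segmentNuclei <- function(od, params = segParams()) {
  stopifnot(is(od, "ODImage"), is(params, "SegParams"))
  validObject(params)
  total <- od@hema + od@dab
  d <- dim(total)
  zero <- matrix(0L, d[1], d[2])
  if (max(total) <= params@minNuclearOD) return(zero)
  sigma <- params@smoothingSigmaUm / od@mpp
  sm <- if (sigma >= 0.3)
    EBImage::imageData(EBImage::gblur(EBImage::Image(total), sigma = sigma))
  else total
  sm[sm < 0] <- 0    # Gaussian ringing can dip just below zero
  # Otsu on the square-root-compressed map: detection should separate
  # tissue from background, not pale from dark nuclei, so the intensity
  # axis is compressed before choosing the cut.
  cm <- sqrt(sm)
  thr <- EBImage::otsu(EBImage::Image(cm), range = c(0, max(cm)),
                       levels = 256L)
  thr <- max(thr, sqrt(params@minNuclearOD))
  fg <- cm > thr
  if (!any(fg)) return(zero)
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(fg * 1)))
  sep <- params@minPeakSeparationUm / od@mpp
  peaks <- .localMaxima(dist, sep, fg)
  if (!nrow(peaks)) return(zero)
  seeds <- zero
  seeds[cbind(peaks[, 1], peaks[, 2])] <- seq_len(nrow(peaks))
  relief <- max(dist) - dist
  lab <- EBImage::propagate(EBImage::Image(relief),
                            seeds = EBImage::Image(seeds),
                            mask = EBImage::Image(fg * 1) > 0)
  matrix(as.integer(EBImage::imageData(lab)), d[1], d[2])
}

#' Extract per-nucleus records with inclusion filtering
#'
#' One record per labelled region: centroid, physical area, eccentricity
#' (from the eigenvalues of the pixel-coordinate covariance; 0 for a disk,
#' `sqrt(1 - (b/a)^2)` for an ellipse with axis ratio a:b), and mean
#' hematoxylin / DAB optical densities. Mean ODs are measured on the
#' region's morphological core (pixels farther than the smoothing radius
#' from the outer foreground boundary) so that the pale halo a smoothed
#' threshold adds around each nucleus does not dilute its intensity; thin
#' regions without core pixels fall back to all pixels. Inclusion requires
#' `minAreaUm2 <= area <= maxAreaUm2` and `eccentricity < maxEccentricity`;
#' size violations take precedence over the spindle (shape) reason.
#'
#' @param mask integer label matrix from [segmentNuclei()].
#' @param od the [ODImage] the mask was computed from (same shape).
#' @param params a [SegParams] object.
#' @return data.frame with one row per label: `label`, `row`, `col`
#'   (centroid, pixel coordinates), `areaUm2`, `eccentricity`, `meanDabOD`,
#'   `meanHemaOD`, `included`, `exclusionReason` (one of `none`,
#'   `too_small`, `too_large`, `spindle`).
#' @export
extractRecords <- function(mask, od, params = segParams()) {
  stopifnot(is(od, "ODImage"), is(params, "SegParams"))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(od@hema)))
    stop("mask and od must share their shape")
  idx <- which(mask > 0)
  empty <- data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      areaUm2 = numeric(0), eccentricity = numeric(0),
                      meanDabOD = numeric(0), meanHemaOD = numeric(0),
                      included = logical(0),
                      exclusionReason = character(0),
                      stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  lab <- mask[idx]
  ij <- arrayInd(idx, dim(mask))
  labs <- sort(unique(lab))
  g <- match(lab, labs)
  n <- as.vector(rowsum(rep(1, length(g)), g))
  sr <- as.vector(rowsum(ij[, 1], g)); sc <- as.vector(rowsum(ij[, 2], g))
  mr <- sr / n; mc <- sc / n
  # central second moments (population) for eccentricity
  srr <- as.vector(rowsum(ij[, 1]^2, g)) / n - mr^2
  scc <- as.vector(rowsum(ij[, 2]^2, g)) / n - mc^2
  src <- as.vector(rowsum(ij[, 1] * ij[, 2], g)) / n - mr * mc
  tr <- srr + scc
  det2 <- srr * scc - src^2
  disc <- pmax(tr^2 / 4 - det2, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  ecc <- ifelse(l1 <= 1e-12, 0, sqrt(pmax(1 - l2 / l1, 0)))
  area <- n * od@mpp^2
  # intensity on the morphological core: trim the outer halo added by the
  # smoothed detection threshold before averaging
  coreMargin <- params@smoothingSigmaUm / od@mpp + 1
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image((mask > 0) * 1)))
  core <- dt[idx] > coreMargin
  nCore <- as.vector(rowsum(as.numeric(core), g))
  dabCore <- as.vector(rowsum(od@dab[idx] * core, g))
  hemaCore <- as.vector(rowsum(od@hema[idx] * core, g))
  mDab <- ifelse(nCore > 0, dabCore / nCore,
                 as.vector(rowsum(od@dab[idx], g)) / n)
  mHema <- ifelse(nCore > 0, hemaCore / nCore,
                  as.vector(rowsum(od@hema[idx], g)) / n)
  reason <- rep("none", length(labs))
  reason[area > params@maxAreaUm2] <- "too_large"
  reason[area < params@minAreaUm2] <- "too_small"
  reason[reason == "none" & ecc >= params@maxEccentricity] <- "spindle"
  data.frame(label = labs, row = mr, col = mc, areaUm2 = area,
             eccentricity = ecc, meanDabOD = mDab, meanHemaOD = mHema,
             included = reason == "none", exclusionReason = reason,
             stringsAsFactors = FALSE)
}
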