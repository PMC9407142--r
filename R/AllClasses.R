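#' @import methods
NULL

GRADE_LEVELS <- c("G1", "G2", "G3")
EXCLUSION_REASONS <- c("none", "too_small", "too_large", "spindle")

#' RGBField: one high-power brightfield IHC field
#'
#' An 8-bit RGB image of a single microscope field together with its spatial
#' calibration (microns per pixel). This is the unit of analysis for Ki-67
#' scoring: a case is scored over a set of such fields (conventionally at
#' least 10 high-power fields at 40x).
#'
#' @slot pixels numeric H x W x 3 array, channel intensities in [0, 255].
#' @slot mpp microns per pixel (> 0).
#' @slot fieldId opaque field identifier.
#' @exportClass RGBField
setClass("RGBField",
  representation(pixels = "array", mpp = "numeric", fieldId = "character"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (dim(p)[1] < 1L || dim(p)[2] < 1L)
      return("image must have at least one row and one column")
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      return("channel values must lie in [0, 255]")
    if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0)
      return("mpp must be a single positive number")
    if (length(object@fieldId) != 1L)
      return("fieldId must be a single string")
    TRUE
  }
)

#' ODImage: per-stain optical-density concentration maps
#'
#' Result of colour deconvolution of an [RGBField]: one map per stain
#' (hematoxylin, DAB, residual) in optical-density units, sharing the source
#' field's spatial calibration. All nuclear intensity measurement happens on
#' these maps.
#'
#' @slot hema,dab,residual numeric H x W matrices, finite and >= 0.
#' @slot mpp microns per pixel inherited from the source field.
#' @exportClass ODImage
setClass("ODImage",
  representation(hema = "matrix", dab = "matrix", residual = "matrix",
                 mpp = "numeric"),
  validity = function(object) {
    d <- dim(object@hema)
    if (!identical(d, dim(object@dab)) || !identical(d, dim(object@residual)))
      return("hema, dab and residual maps must share their shape")
    for (nm in c("hema", "dab", "residual")) {
      m <- slot(object, nm)
      if (anyNA(m) || any(!is.finite(m)))
        return(sprintf("%s map contains non-finite values", nm))
      if (min(m) < 0)
        return(sprintf("%s map contains negative optical densities", nm))
    }
    if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0)
      return("mpp must be a single positive number")
    TRUE
  }
)

#' SegParams: nucleus segmentation and inclusion parameters
#'
#' Geometric thresholds are specified in physical units (micrometres) and
#' converted through the field's mpp, so behaviour is independent of
#' magnification. The size floor and the eccentricity ceiling together
#' operationalise the exclusion of small, spindle-shaped stromal nuclei,
#' which stain pale and would otherwise inflate the positive count.
#'
#' @slot minAreaUm2,maxAreaUm2 nucleus area acceptance window (um^2).
#' @slot maxEccentricity inclusion requires eccentricity strictly below this
#'   (spindle filter); in [0, 1).
#' @slot smoothingSigmaUm Gaussian smoothing applied to the nuclear OD map
#'   before thresholding (um).
#' @slot minPeakSeparationUm minimum separation between watershed markers (um).
#' @slot minNuclearOD noise floor on the smoothed nuclear OD: the Otsu
#'   threshold is never taken below this, so blank fields yield no objects.
#' @exportClass SegParams
setClass("SegParams",
  representation(minAreaUm2 = "numeric", maxAreaUm2 = "numeric",
                 maxEccentricity = "numeric", smoothingSigmaUm = "numeric",
                 minPeakSeparationUm = "numeric", minNuclearOD = "numeric"),
  prototype(minAreaUm2 = 20, maxAreaUm2 = 400, maxEccentricity = 0.95,
            smoothingSigmaUm = 0.5, minPeakSeparationUm = 3,
            minNuclearOD = 0.1),
  validity = function(object) {
    if (!(object@minAreaUm2 > 0 && object@minAreaUm2 < object@maxAreaUm2))
      return("need 0 < minAreaUm2 < maxAreaUm2")
    if (object@maxEccentricity < 0 || object@maxEccentricity >= 1)
      return("maxEccentricity must lie in [0, 1)")
    if (object@smoothingSigmaUm < 0)
      return("smoothingSigmaUm must be >= 0")
    if (object@minPeakSeparationUm <= 0)
      return("minPeakSeparationUm must be > 0")
    if (object@minNuclearOD < 0)
      return("minNuclearOD must be >= 0")
    TRUE
  }
)

#' IntensityThresholds: DAB optical-density class boundaries
#'
#' Mean nuclear DAB OD below `tNeg` is negative; in [`tNeg`, `tHigh`) is
#' "low" (pale brown); at or above `tHigh` is "high" (dark brown / black).
#' A boundary value belongs to the upper class. The traditional Ki-67 index
#' counts low + high; the semiquantal index counts high only.
#'
#' @slot tNeg,tHigh optical-density thresholds, 0 < tNeg < tHigh.
#' @exportClass IntensityThresholds
setClass("IntensityThresholds",
  representation(tNeg = "numeric", tHigh = "numeric"),
  prototype(tNeg = 0.15, tHigh = 0.60),
  validity = function(object) {
    if (!(object@tNeg > 0 && object@tNeg < object@tHigh))
      return("need 0 < tNeg < tHigh")
    TRUE
  }
)

#' FieldScore: pooled nucleus counts for one field
#'
#' @slot fieldId field identifier.
#' @slot nTotal,nNegative,nLow,nHigh counts over included nuclei only;
#'   the three class counts partition nTotal.
#' @exportClass FieldScore
setClass("FieldScore",
  representation(fieldId = "character", nTotal = "integer",
                 nNegative = "integer", nLow = "integer", nHigh = "integer"),
  validity = function(object) {
    cnt <- c(object@nTotal, object@nNegative, object@nLow, object@nHigh)
    if (anyNA(cnt) || any(cnt < 0L))
      return("counts must be non-negative")
    if (object@nNegative + object@nLow + object@nHigh != object@nTotal)
      return("class counts must sum to nTotal")
    TRUE
  }
)

#' CaseScore: pooled case-level Ki-67 indices
#'
#' Indices are pooled over fields (sum of numerators over sum of
#' denominators), so fields are weighted by their cellularity. The validity
#' flag records whether the case meets the minimum-material rules (at least
#' 10 fields, more than 100 nuclei); failing them flags the score rather
#' than refusing it.
#'
#' @slot caseId case identifier.
#' @slot fields list of [FieldScore] pooled into this case.
#' @slot traditionalIndex percent of included nuclei with any discernible
#'   staining (low + high), in [0, 100].
#' @slot semiquantalIndex percent of included nuclei with high-intensity
#'   staining only, in [0, 100]; never exceeds traditionalIndex.
#' @slot mitoticCount mitotic figures per 10 high-power fields (input, not
#'   measured from pixels).
#' @slot nFields number of fields pooled.
#' @slot valid FALSE when the minimum-material rules are not met.
#' @slot validityNotes human-readable reasons when valid is FALSE.
#' @exportClass CaseScore
setClass("CaseScore",
  representation(caseId = "character", fields = "list",
                 traditionalIndex = "numeric", semiquantalIndex = "numeric",
                 mitoticCount = "integer", nFields = "integer",
                 valid = "logical", validityNotes = "character"),
  validity = function(object) {
    ti <- object@traditionalIndex; si <- object@semiquantalIndex
    if (ti < 0 || ti > 100 || si < 0 || si > 100)
      return("indices must lie in [0, 100]")
    if (si > ti + 1e-9)
      return("semiquantalIndex cannot exceed traditionalIndex")
    if (object@mitoticCount < 0L)
      return("mitoticCount must be >= 0")
    if (!all(vapply(object@fields, is, logical(1), class2 = "FieldScore")))
      return("fields must be a list of FieldScore objects")
    TRUE
  }
)

#' GradeResult: WHO grade with its two components
#'
#' The overall grade is the higher of the Ki-67 component and the mitotic
#' component under the ordering G1 < G2 < G3 (the WHO "or" rule).
#'
#' @slot grade,ki67Grade,mitoticGrade one of "G1", "G2", "G3".
#' @exportClass GradeResult
setClass("GradeResult",
  representation(grade = "character", ki67Grade = "character",
                 mitoticGrade = "character"),
  validity = function(object) {
    g <- c(object@grade, object@ki67Grade, object@mitoticGrade)
    if (!all(g %in% GRADE_LEVELS))
      return("grades must be one of G1, G2, G3")
    if (match(object@grade, GRADE_LEVELS) !=
        max(match(object@ki67Grade, GRADE_LEVELS),
            match(object@mitoticGrade, GRADE_LEVELS)))
      return("grade must be the max of its components")
    TRUE
  }
)

#' ReclassTable: paired grade cross-tabulation
#'
#' Rows are the grade under the traditional index, columns under the
#' semiquantal index; each patient contributes one cell. Marginals reproduce
#' the per-method grade distributions exactly.
#'
#' @slot counts 3 x 3 integer matrix with dimnames G1..G3.
#' @slot n total number of patients.
#' @exportClass ReclassTable
setClass("ReclassTable",
  representation(counts = "matrix", n = "integer"),
  validity = function(object) {
    cnt <- object@counts
    if (!identical(dim(cnt), c(3L, 3L)))
      return("counts must be 3 x 3")
    if (any(cnt < 0L))
      return("counts must be non-negative")
    if (sum(cnt) != object@n)
      return("counts must sum to n")
    TRUE
  }
)

#' StatResult: a test statistic with df, p-value and method label
#'
#' @slot statistic value of the test statistic.
#' @slot df degrees of freedom (NA where the test has none).
#' @slot pValue two-tailed p-value in [0, 1].
#' @slot method human-readable description of the test.
#' @exportClass StatResult
setClass("StatResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 method = "character"),
  validity = function(object) {
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      return("pValue must lie in [0, 1]")
    TRUE
  }
)

#' SurvivalCurve: Kaplan-Meier product-limit estimate
#'
#' Stepwise survival estimate over the distinct event times of one group.
#' Censored subjects at an event time are still at risk at that time
#' (events precede censorings at ties).
#'
#' @slot times sorted distinct event times.
#' @slot survival product-limit estimates, non-increasing in [0, 1].
#' @slot atRisk number at risk just before each event time.
#' @slot events number of events at each time.
#' @exportClass SurvivalCurve
setClass("SurvivalCurve",
  representation(times = "numeric", survival = "numeric",
                 atRisk = "integer", events = "integer"),
  validity = function(object) {
    k <- length(object@times)
    if (length(object@survival) != k || length(object@atRisk) != k ||
        length(object@events) != k)
      return("times, survival, atRisk and events must have equal length")
    if (k > 0) {
      if (is.unsorted(object@times, strictly = TRUE))
        return("times must be strictly increasing")
      if (any(diff(object@survival) > 1e-12))
        return("survival must be non-increasing")
      if (max(object@survival) > 1 + 1e-12 || min(object@survival) < -1e-12)
        return("survival must lie in [0, 1]")
    }
    TRUE
  }
)

#' FieldSimParams: synthetic H-DAB field generator settings
#'
#' Describes one rendered field: tumour nuclei as near-circular disks whose
#' DAB optical density is drawn from class-conditional means (negative /
#' low "pale brown" / high "dark brown-black"), plus optional spindle-shaped
#' stromal confounders carrying a pale false-positive stain. Default class
#' OD means (0.02 / 0.35 / 0.90) put "low" midway between the default
#' intensity thresholds and "high" well above the upper one.
#'
#' @slot widthPx,heightPx canvas size in pixels.
#' @slot mpp microns per pixel.
#' @slot nTumorNuclei number of tumour nuclei to place.
#' @slot classProportions probabilities (negative, low, high), summing to 1.
#' @slot dabODByClass mean DAB OD per class (negative, low, high).
#' @slot dabODJitterSD Gaussian jitter of per-nucleus DAB OD.
#' @slot hemaODMean,hemaODJitterSD hematoxylin counterstain OD.
#' @slot nucleusRadiusUm tumour nucleus radius range (um), sampled uniformly.
#' @slot nStromal number of stromal (spindle) nuclei.
#' @slot stromalAxisRatio major/minor axis ratio of stromal nuclei (>= 4).
#' @slot stromalMinorAxisUm stromal semi-minor axis (um).
#' @slot stromalDabOD pale false-positive DAB OD carried by stromal nuclei.
#' @slot noiseSD additive Gaussian noise on the 0-255 RGB scale.
#' @slot maxOverlapFraction allowed centre-distance shortfall as a fraction
#'   of the sum of radii (0 = no overlap).
#' @slot i0 background (blank) intensity.
#' @slot seed generator seed; all draws flow from named sub-streams.
#' @exportClass FieldSimParams
setClass("FieldSimParams",
  representation(widthPx = "integer", heightPx = "integer", mpp = "numeric",
                 nTumorNuclei = "integer", classProportions = "numeric",
                 dabODByClass = "numeric", dabODJitterSD = "numeric",
                 hemaODMean = "numeric", hemaODJitterSD = "numeric",
                 nucleusRadiusUm = "numeric", nStromal = "integer",
                 stromalAxisRatio = "numeric", stromalMinorAxisUm = "numeric",
                 stromalDabOD = "numeric", noiseSD = "numeric",
                 maxOverlapFraction = "numeric", i0 = "integer",
                 seed = "integer"),
  prototype(widthPx = 400L, heightPx = 400L, mpp = 0.5, nTumorNuclei = 120L,
            classProportions = c(0.85, 0.10, 0.05),
            dabODByClass = c(0.02, 0.35, 0.90), dabODJitterSD = 0.05,
            hemaODMean = 0.45, hemaODJitterSD = 0.05,
            nucleusRadiusUm = c(3, 5), nStromal = 0L,
            stromalAxisRatio = 5, stromalMinorAxisUm = 1.0,
            stromalDabOD = 0.30, noiseSD = 2, maxOverlapFraction = 0,
            i0 = 255L, seed = 1L),
  validity = function(object) {
    if (object@widthPx < 1L || object@heightPx < 1L)
      return("canvas must be at least 1 x 1")
    if (object@mpp <= 0) return("mpp must be > 0")
    if (object@nTumorNuclei < 0L || object@nStromal < 0L)
      return("nucleus counts must be >= 0")
    p <- object@classProportions
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      return("classProportions must be 3 non-negative values summing to 1")
    if (length(object@dabODByClass) != 3L || any(object@dabODByClass < 0))
      return("dabODByClass must be 3 non-negative ODs")
    if (object@hemaODMean < 0 || object@stromalDabOD < 0)
      return("ODs must be >= 0")
    r <- object@nucleusRadiusUm
    if (length(r) != 2L || r[1] <= 0 || r[2] < r[1])
      return("nucleusRadiusUm must be an increasing positive range")
    if (object@stromalAxisRatio < 1)
      return("stromalAxisRatio must be >= 1")
    if (object@maxOverlapFraction < 0 || object@maxOverlapFraction >= 1)
      return("maxOverlapFraction must lie in [0, 1)")
    if (object@i0 < 1L || object@i0 > 255L)
      return("i0 must lie in [1, 255]")
    TRUE
  }
)

#' CohortSimParams: synthetic patient-cohort generator settings
#'
#' Generates a GEP-NET-like cohort: a latent grade per patient, a
#' grade-conditional log-normal semiquantal Ki-67 index (log-normal because
#' observed index distributions are strongly right-skewed, with sd larger
#' than the mean), a non-negative log-normal "low-stain excess" that turns
#' the semiquantal index into the traditional one, a Poisson mitotic count
#' linked to the semiquantal index, and exponential overall-survival times
#' with grade-dependent hazard under uniform administrative censoring.
#'
#' @slot nPatients cohort size.
#' @slot pancreaticFraction probability a tumour is pancreatic.
#' @slot gradeMixture probabilities over latent (G1, G2, G3).
#' @slot indexMeanlog,indexSdlog per-grade log-normal parameters of the
#'   semiquantal index; draws are clipped into the grade's index band.
#' @slot excessMeanlog,excessSdlog log-normal parameters of the non-negative
#'   low-stain excess (traditional = semiquantal + excess, capped at 100).
#' @slot mitosisRate Poisson rate multiplier: mc ~ Pois(rate * semiquantal).
#' @slot hazardByGrade exponential OS hazards per latent grade (1/year).
#' @slot followupRangeYears administrative censoring drawn uniformly here.
#' @slot ageMeanYears,ageSdYears Gaussian age distribution.
#' @slot dfiMeanlog,dfiSdlog log-normal disease-free interval (independent
#'   of the proliferation measures).
#' @slot seed generator seed.
#' @exportClass CohortSimParams
setClass("CohortSimParams",
  representation(nPatients = "integer", pancreaticFraction = "numeric",
                 gradeMixture = "numeric", indexMeanlog = "numeric",
                 indexSdlog = "numeric", excessMeanlog = "numeric",
                 excessSdlog = "numeric", mitosisRate = "numeric",
                 hazardByGrade = "numeric", followupRangeYears = "numeric",
                 ageMeanYears = "numeric", ageSdYears = "numeric",
                 dfiMeanlog = "numeric", dfiSdlog = "numeric",
                 seed = "integer"),
  prototype(nPatients = 87L, pancreaticFraction = 0.55,
            gradeMixture = c(0.61, 0.30, 0.09),
            indexMeanlog = log(c(1.2, 8, 35)),
            indexSdlog = c(0.70, 0.55, 0.35),
            excessMeanlog = 1.35, excessSdlog = 0.9,
            mitosisRate = 0.55,
            hazardByGrade = c(0.008, 0.06, 0.30),
            followupRangeYears = c(1.6, 9.5),
            ageMeanYears = 64.5, ageSdYears = 14.7,
            dfiMeanlog = log(4.0), dfiSdlog = 0.5,
            seed = 1L),
  validity = function(object) {
    if (object@nPatients < 1L) return("nPatients must be >= 1")
    if (object@pancreaticFraction < 0 || object@pancreaticFraction > 1)
      return("pancreaticFraction must lie in [0, 1]")
    p <- object@gradeMixture
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      return("gradeMixture must be 3 non-negative values summing to 1")
    if (length(object@indexMeanlog) != 3L || length(object@indexSdlog) != 3L)
      return("index distribution parameters must have length 3")
    if (any(object@indexSdlog < 0) || object@excessSdlog < 0)
      return("sdlog parameters must be >= 0")
    if (object@mitosisRate < 0) return("mitosisRate must be >= 0")
    h <- object@hazardByGrade
    if (length(h) != 3L || any(h <= 0))
      return("hazardByGrade must be 3 positive rates")
    f <- object@followupRangeYears
    if (length(f) != 2L || f[1] < 0 || f[2] < f[1])
      return("followupRangeYears must be an increasing non-negative range")
    TRUE
  }
)
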