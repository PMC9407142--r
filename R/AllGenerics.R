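#' @rdname accessors
#' @export
setGeneric("mpp", function(x) standardGeneric("mpp"))
#' @rdname accessors
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))
#' @rdname accessors
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setGeneric("hemaOD", function(x) standardGeneric("hemaOD"))
#' @rdname accessors
#' @export
setGeneric("dabOD", function(x) standardGeneric("dabOD"))
#' @rdname accessors
#' @export
setGeneric("residualOD", function(x) standardGeneric("residualOD"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x, ...) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("traditionalIndex", function(x) standardGeneric("traditionalIndex"))
#' @rdname accessors
#' @export
setGeneric("semiquantalIndex", function(x) standardGeneric("semiquantalIndex"))
#' @rdname accessors
#' @export
setGeneric("mitoticCount", function(x) standardGeneric("mitoticCount"))
#' @rdname accessors
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))
#' @rdname accessors
#' @export
setGeneric("grade", function(x) standardGeneric("grade"))
#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("marginalPercents", function(x, ...) standardGeneric("marginalPercents"))

#' Accessors for semiKi67 classes
#'
#' Small read-only accessors for the package's S4 containers. `mpp()` and
#' `fieldId()` work on both [RGBField] and [ODImage]; `counts()` returns the
#' per-class nucleus counts of a [FieldScore] or the cross-tabulation of a
#' [ReclassTable]; index accessors work on [CaseScore].
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @return the slot value (see each class's documentation).
#' @name accessors
#' @aliases mpp fieldId pixelData hemaOD dabOD residualOD counts
#'   traditionalIndex semiquantalIndex mitoticCount isValid grade statistic
#'   pValue marginalPercents
NULL

setMethod("mpp", "RGBField", function(x) x@mpp)
setMethod("mpp", "ODImage", function(x) x@mpp)
setMethod("fieldId", "RGBField", function(x) x@fieldId)
setMethod("fieldId", "FieldScore", function(x) x@fieldId)
setMethod("pixelData", "RGBField", function(x) x@pixels)
setMethod("hemaOD", "ODImage", function(x) x@hema)
setMethod("dabOD", "ODImage", function(x) x@dab)
setMethod("residualOD", "ODImage", function(x) x@residual)

setMethod("counts", "FieldScore", function(x, ...)
  c(total = x@nTotal, negative = x@nNegative, low = x@nLow, high = x@nHigh))
setMethod("counts", "ReclassTable", function(x, ...) x@counts)

setMethod("traditionalIndex", "CaseScore", function(x) x@traditionalIndex)
setMethod("semiquantalIndex", "CaseScore", function(x) x@semiquantalIndex)
setMethod("mitoticCount", "CaseScore", function(x) x@mitoticCount)
setMethod("isValid", "CaseScore", function(x) x@valid)
setMethod("grade", "GradeResult", function(x) x@grade)
setMethod("statistic", "StatResult", function(x) x@statistic)
setMethod("pValue", "StatResult", function(x) x@pValue)

setMethod("show", "RGBField", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBField '%s': %d x %d px, %.3f um/px (%.0f x %.0f um)\n",
              object@fieldId, d[1], d[2], object@mpp,
              d[1] * object@mpp, d[2] * object@mpp))
})

setMethod("show", "ODImage", function(object) {
  d <- dim(object@hema)
  cat(sprintf(
    "ODImage: %d x %d px, %.3f um/px | max OD hema %.2f, dab %.2f\n",
    d[1], d[2], object@mpp, max(object@hema), max(object@dab)))
})

setMethod("show", "FieldScore", function(object) {
  cat(sprintf(
    "FieldScore '%s': %d nuclei (neg %d, low %d, high %d)\n",
    object@fieldId, object@nTotal, object@nNegative, object@nLow,
    object@nHigh))
})

setMethod("show", "CaseScore", function(object) {
  cat(sprintf(
    "CaseScore '%s': traditional %.1f%%, semiquantal %.1f%% over %d field(s); mitoses %d /10 HPF%s\n",
    object@caseId, object@traditionalIndex, object@semiquantalIndex,
    object@nFields, object@mitoticCount,
    if (object@valid) "" else
      paste0(" [NOT VALID: ", paste(object@validityNotes, collapse = "; "),
             "]")))
})

setMethod("show", "GradeResult", function(object) {
  cat(sprintf("WHO grade %s (Ki-67 component %s, mitotic component %s)\n",
              object@grade, object@ki67Grade, object@mitoticGrade))
})

setMethod("show", "ReclassTable", function(object) {
  cat(sprintf("ReclassTable (n = %d): traditional grade (rows) vs semiquantal grade (cols)\n",
              object@n))
  print(object@counts)
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              object@method, object@statistic,
              if (is.na(object@df)) "NA" else format(object@df),
              object@pValue))
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve: %d event time(s)%s\n", length(object@times),
              if (length(object@times))
                sprintf(", final S = %.3f", min(object@survival)) else ""))
})
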