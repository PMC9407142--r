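#' Classify nuclear staining intensity
#'
#' Assigns each included nucleus to one of three DAB intensity classes:
#' `negative` (mean DAB OD below `tNeg`), `low` (pale brown; at least
#' `tNeg` but below `tHigh`) or `high` (dark brown / black; at least
#' `tHigh`). Boundary values belong to the upper class.
#'
#' @param x a nucleus record data.frame (from [extractRecords()]), or a
#'   numeric vector of mean DAB optical densities. Records must all be
#'   included: excluded nuclei never enter the counts, and passing one is
#'   an error.
#' @param th an [IntensityThresholds] object.
#' @return factor with levels `negative`, `low`, `high`.
#' @examples
#' classifyIntensity(c(0, 0.3, 0.6))
#' @export
classifyIntensity <- function(x, th = intensityThresholds()) {
  stopifnot(is(th, "IntensityThresholds"))
  validObject(th)
  if (is.data.frame(x)) {
    if (!all(x$included))
      stop("excluded nuclei cannot be classified; filter to included records")
    x <- x$meanDabOD
  }
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop("mean DAB OD must be non-negative numeric")
  cls <- ifelse(x >= th@tHigh, "high", ifelse(x >= th@tNeg, "low", "negative"))
  factor(cls, levels = c("negative", "low", "high"))
}

#' Score one field
#'
#' Counts included nuclei by intensity class. Excluded records (too small,
#' too large, spindle-shaped) are dropped before counting.
#'
#' @param records nucleus record data.frame from [extractRecords()]
#'   (may be empty).
#' @param th an [IntensityThresholds] object.
#' @param fieldId identifier for the resulting score.
#' @return a [FieldScore].
#' @export
scoreField <- function(records, th = intensityThresholds(),
                       fieldId = "field") {
  if (is.null(records) || nrow(records) == 0L) {
    return(new("FieldScore", fieldId = as.character(fieldId), nTotal = 0L,
               nNegative = 0L, nLow = 0L, nHigh = 0L))
  }
  inc <- records[records$included, , drop = FALSE]
  if (nrow(inc) == 0L)
    return(new("FieldScore", fieldId = as.character(fieldId), nTotal = 0L,
               nNegative = 0L, nLow = 0L, nHigh = 0L))
  cls <- classifyIntensity(inc, th)
  tab <- table(cls)
  new("FieldScore", fieldId = as.character(fieldId),
      nTotal = nrow(inc),
      nNegative = as.integer(tab[["negative"]]),
      nLow = as.integer(tab[["low"]]),
      nHigh = as.integer(tab[["high"]]))
}

#' Score a case from its field scores
#'
#' Pools counts across fields (sum of numerators over sum of denominators,
#' so fields are weighted by cellularity) and computes both indices:
#' traditional = percent of nuclei with any discernible staining
#' (low + high); semiquantal = percent with high-intensity staining only.
#' A case with fewer than 10 fields or 100 or fewer nuclei in total is
#' scored but flagged invalid, with notes explaining why.
#'
#' @param fields list of [FieldScore] objects.
#' @param mitoticCount mitotic figures per 10 HPF (integer >= 0); this is an
#'   input measured on H&E sections, not computed from pixels.
#' @param caseId identifier.
#' @param minFields,minNuclei validity rules (defaults 10 fields, > 100
#'   nuclei).
#' @return a [CaseScore]. Zero nuclei across all fields is an error: the
#'   indices are undefined.
#' @export
scoreCase <- function(fields, mitoticCount, caseId = "case",
                      minFields = 10L, minNuclei = 100L) {
  if (is(fields, "FieldScore")) fields <- list(fields)
  stopifnot(all(vapply(fields, is, logical(1), class2 = "FieldScore")))
  mitoticCount <- as.integer(mitoticCount)
  if (is.na(mitoticCount) || mitoticCount < 0L)
    stop("mitoticCount must be a non-negative integer")
  tot <- sum(vapply(fields, function(f) f@nTotal, integer(1)))
  if (tot == 0L)
    stop("empty case: no included nuclei across fields, indices undefined")
  nLow <- sum(vapply(fields, function(f) f@nLow, integer(1)))
  nHigh <- sum(vapply(fields, function(f) f@nHigh, integer(1)))
  notes <- character(0)
  if (length(fields) < minFields)
    notes <- c(notes, sprintf("only %d field(s) scored; minimum is %d",
                              length(fields), minFields))
  if (tot <= minNuclei)
    notes <- c(notes, sprintf("only %d nuclei counted; more than %d required",
                              tot, minNuclei))
  new("CaseScore", caseId = as.character(caseId), fields = fields,
      traditionalIndex = 100 * (nLow + nHigh) / tot,
      semiquantalIndex = 100 * nHigh / tot,
      mitoticCount = mitoticCount, nFields = length(fields),
      valid = length(notes) == 0L, validityNotes = notes)
}

#' WHO grade component from the Ki-67 index
#'
#' G1 for an index below 3%, G2 from 3% to 20% inclusive, G3 above 20%.
#' The gap between the printed G1 ceiling (2%) and G2 floor (3%) is closed
#' at 3% (WHO 2019 convention); override via `g1Ceiling`.
#'
#' @param index Ki-67 index in percent, in [0, 100]; vectorized.
#' @param g1Ceiling indices strictly below this are G1 (default 3).
#' @return ordered factor with levels G1 < G2 < G3.
#' @examples
#' gradeFromKi67(c(2, 3, 20, 20.01))
#' @export
gradeFromKi67 <- function(index, g1Ceiling = 3) {
  if (!is.numeric(index) || anyNA(index) || any(index < 0 | index > 100))
    stop("Ki-67 index must lie in [0, 100]")
  g <- ifelse(index < g1Ceiling, "G1", ifelse(index <= 20, "G2", "G3"))
  factor(g, levels = GRADE_LEVELS, ordered = TRUE)
}

#' WHO grade component from the mitotic count
#'
#' G1 for 0-1 mitoses per 10 HPF, G2 for 2-20, G3 above 20.
#'
#' @param mc mitotic count per 10 HPF (non-negative integers); vectorized.
#' @return ordered factor with levels G1 < G2 < G3.
#' @export
gradeFromMitoses <- function(mc) {
  if (!is.numeric(mc) || anyNA(mc) || any(mc < 0))
    stop("mitotic count must be >= 0")
  g <- ifelse(mc <= 1, "G1", ifelse(mc <= 20, "G2", "G3"))
  factor(g, levels = GRADE_LEVELS, ordered = TRUE)
}

#' Combined WHO grade
#'
#' The WHO rule assigns the grade by mitotic rate *or* Ki-67 index; the
#' higher of the two components wins (G1 < G2 < G3).
#'
#' @param index Ki-67 index in percent.
#' @param mc mitotic count per 10 HPF.
#' @param g1Ceiling passed to [gradeFromKi67()].
#' @return for scalar inputs, a [GradeResult]; for vectors, a data.frame
#'   with columns `grade`, `ki67Grade`, `mitoticGrade` (ordered factors).
#' @examples
#' combinedGrade(1.0, 25)  # mitoses dominate: G3
#' @export
combinedGrade <- function(index, mc, g1Ceiling = 3) {
  if (length(index) != length(mc))
    stop("index and mc must have equal length")
  ki <- gradeFromKi67(index, g1Ceiling = g1Ceiling)
  mi <- gradeFromMitoses(mc)
  g <- factor(GRADE_LEVELS[pmax(as.integer(ki), as.integer(mi))],
              levels = GRADE_LEVELS, ordered = TRUE)
  if (length(index) == 1L)
    return(new("GradeResult", grade = as.character(g),
               ki67Grade = as.character(ki), mitoticGrade = as.character(mi)))
  data.frame(grade = g, ki67Grade = ki, mitoticGrade = mi)
}

#' Grade a scored case under both evaluation methods
#'
#' @param case a [CaseScore].
#' @param g1Ceiling passed to [gradeFromKi67()].
#' @return list with [GradeResult]s `traditional` and `semiquantal`.
#' @export
gradeCase <- function(case, g1Ceiling = 3) {
  stopifnot(is(case, "CaseScore"))
  list(traditional = combinedGrade(case@traditionalIndex, case@mitoticCount,
                                   g1Ceiling = g1Ceiling),
       semiquantal = combinedGrade(case@semiquantalIndex, case@mitoticCount,
                                   g1Ceiling = g1Ceiling))
}
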