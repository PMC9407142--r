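COHORT_COLUMNS <- c("case_id", "age_years", "sex", "location", "dfi_years",
                    "os_years", "event", "traditional_index",
                    "semiquantal_index", "mitotic_count")

#' Read a brightfield field image
#'
#' Reads PNG or TIFF into an [RGBField]. The spatial calibration comes from
#' the `mpp` argument or, when absent, from a sidecar JSON next to the
#' image (`<image>.json` or `<stem>.json`) containing `{"mpp": ...}`.
#' An alpha channel, if present, is dropped.
#'
#' @param path image path (.png, .tif or .tiff).
#' @param mpp microns per pixel; overrides any sidecar value.
#' @param fieldId identifier (default: the file stem).
#' @return an [RGBField].
#' @export
readFieldImage <- function(path, mpp = NULL, fieldId = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported image format '.%s'", ext)))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) stop("image must have 3 colour channels")
  if (is.null(mpp)) {
    stem <- tools::file_path_sans_ext(path)
    for (cand in c(paste0(path, ".json"), paste0(stem, ".json"))) {
      if (file.exists(cand)) {
        side <- jsonlite::read_json(cand)
        if (!is.null(side$mpp)) { mpp <- as.numeric(side$mpp); break }
      }
    }
  }
  if (is.null(mpp))
    stop(sprintf("missing mpp for '%s': pass mpp= or provide a sidecar JSON",
                 path))
  if (is.null(fieldId))
    fieldId <- basename(tools::file_path_sans_ext(path))
  rgbField(round(img * 255), mpp = mpp, fieldId = fieldId)
}

#' Write an RGBField as PNG or TIFF
#'
#' @param field an [RGBField].
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
writeFieldImage <- function(field, path) {
  stopifnot(is(field, "RGBField"))
  img <- field@pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
         stop(sprintf("unsupported image format '.%s'", ext)))
  invisible(path)
}

#' Write a labelled mask as 16-bit TIFF
#'
#' @param mask integer label matrix from [segmentNuclei()].
#' @param path output .tif path.
#' @return the path, invisibly.
#' @export
writeMaskTIFF <- function(mask, path) {
  m <- as.matrix(mask)
  if (max(m) > 65535L) stop("more than 65535 labels cannot be stored")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' The schema (header required):
#' `case_id, age_years, sex, location, dfi_years, os_years, event,
#' traditional_index, semiquantal_index, mitotic_count`; optional columns
#' `grade_traditional`, `grade_semiquantal`, `nec_g3`. Validation errors
#' name the offending row and column.
#'
#' @param path CSV path.
#' @return validated cohort data.frame.
#' @export
readCohortCSV <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read cohort file '%s'", path))
  if (file.size(path) == 0L) stop(sprintf("cohort file '%s' is empty", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop(sprintf("cohort file '%s' has no data rows", path))
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("cohort schema violation: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  df$event <- as.logical(df$event)
  checks <- list(
    list("os_years", function(v) is.finite(v) & v >= 0),
    list("dfi_years", function(v) is.finite(v) & v >= 0),
    list("traditional_index", function(v) is.finite(v) & v >= 0 & v <= 100),
    list("semiquantal_index", function(v) is.finite(v) & v >= 0 & v <= 100),
    list("mitotic_count", function(v) is.finite(v) & v >= 0),
    list("event", function(v) !is.na(v)))
  for (ch in checks) {
    v <- df[[ch[[1]]]]
    if (!is.numeric(v) && ch[[1]] != "event")
      stop(sprintf("cohort schema violation: column '%s' is not numeric",
                   ch[[1]]))
    bad <- which(!ch[[2]](v))
    if (length(bad))
      stop(sprintf("cohort schema violation: row %d, column '%s'",
                   bad[1], ch[[1]]))
  }
  bad <- which(df$semiquantal_index > df$traditional_index + 1e-9)
  if (length(bad))
    stop(sprintf(
      "cohort schema violation: row %d, semiquantal_index exceeds traditional_index",
      bad[1]))
  bad <- which(!df$sex %in% c("female", "male"))
  if (length(bad))
    stop(sprintf("cohort schema violation: row %d, column 'sex'", bad[1]))
  bad <- which(!df$location %in% c("pancreatic", "non_pancreatic"))
  if (length(bad))
    stop(sprintf("cohort schema violation: row %d, column 'location'",
                 bad[1]))
  df
}

#' Default pipeline configuration
#'
#' A single flat list of every tunable in the pipeline, embeddable as JSON.
#' [loadConfig()] reads a JSON file and overrides these defaults; unknown
#' keys are rejected.
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    i0 = 255L,
    stain_matrix = NULL,          # 2x3 or 3x3 row-major override
    min_area_um2 = 20,
    max_area_um2 = 400,
    max_eccentricity = 0.95,
    smoothing_sigma_um = 0.5,
    min_peak_separation_um = 3,
    min_nuclear_od = 0.1,
    t_neg = 0.15,
    t_high = 0.60,
    g1_ceiling = 3,
    min_fields = 10L,
    min_nuclei = 100L,
    dichotomize = "grade_threshold",
    exclude_nec = FALSE,
    seed = 1L)
}

#' @describeIn defaultConfig load a JSON config file over the defaults.
#' @param path JSON file with a subset of the default keys.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop(sprintf("cannot read config '%s'", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(user)] <- user
  cfg
}

.configSegParams <- function(cfg)
  segParams(minAreaUm2 = cfg$min_area_um2, maxAreaUm2 = cfg$max_area_um2,
            maxEccentricity = cfg$max_eccentricity,
            smoothingSigmaUm = cfg$smoothing_sigma_um,
            minPeakSeparationUm = cfg$min_peak_separation_um,
            minNuclearOD = cfg$min_nuclear_od)

.configThresholds <- function(cfg)
  intensityThresholds(tNeg = cfg$t_neg, tHigh = cfg$t_high)

.configMatrix <- function(cfg) {
  if (is.null(cfg$stain_matrix)) return(defaultHDABMatrix())
  m <- cfg$stain_matrix
  if (!is.matrix(m)) m <- matrix(unlist(m), ncol = 3, byrow = TRUE)
  stainMatrix(m)
}

#' Score one field image end to end
#'
#' Reads the image, deconvolves, segments, classifies intensities and
#' returns the field-level counts plus the per-nucleus records.
#'
#' @param path image path.
#' @param mpp microns per pixel (or NULL to use a sidecar JSON).
#' @param config configuration list from [loadConfig()].
#' @param debugMask optional path for a 16-bit TIFF of the label mask.
#' @param debugRecords optional path for a per-nucleus CSV.
#' @return list with `score` (a [FieldScore]), `records` (data.frame) and
#'   `json` (serializable summary).
#' @export
runScoreImage <- function(path, mpp = NULL, config = defaultConfig(),
                          debugMask = NULL, debugRecords = NULL) {
  field <- readFieldImage(path, mpp = mpp)
  od <- fieldToOD(field, m = .configMatrix(config), i0 = config$i0)
  sp <- .configSegParams(config)
  mask <- segmentNuclei(od, sp)
  rec <- extractRecords(mask, od, sp)
  score <- scoreField(rec, .configThresholds(config), fieldId(field))
  if (!is.null(debugMask)) writeMaskTIFF(mask, debugMask)
  if (!is.null(debugRecords)) {
    out <- cbind(field_id = fieldId(field), rec)
    utils::write.csv(out, debugRecords, row.names = FALSE)
  }
  cnt <- counts(score)
  list(score = score, records = rec,
       json = list(field_id = fieldId(field),
                   n_total = unname(cnt[["total"]]),
                   n_negative = unname(cnt[["negative"]]),
                   n_low = unname(cnt[["low"]]),
                   n_high = unname(cnt[["high"]])))
}

#' Score a case from several field images
#'
#' @param paths character vector of image paths (the fields of one case).
#' @param mitoses mitotic count per 10 HPF.
#' @param mpp microns per pixel shared by the fields (or NULL for sidecars).
#' @param config configuration list.
#' @param caseId identifier.
#' @return list with `case` (a [CaseScore]), `grades` and `json`.
#' @export
runScoreCase <- function(paths, mitoses, mpp = NULL,
                         config = defaultConfig(), caseId = "case") {
  if (!length(paths)) stop("no field images supplied")
  scores <- lapply(paths, function(p)
    runScoreImage(p, mpp = mpp, config = config)$score)
  cs <- scoreCase(scores, mitoticCount = mitoses, caseId = caseId,
                  minFields = config$min_fields,
                  minNuclei = config$min_nuclei)
  gr <- gradeCase(cs, g1Ceiling = config$g1_ceiling)
  pooled <- Reduce(`+`, lapply(scores, counts))
  list(case = cs, grades = gr,
       json = list(case_id = cs@caseId,
                   traditional_index = cs@traditionalIndex,
                   semiquantal_index = cs@semiquantalIndex,
                   mitotic_count = cs@mitoticCount,
                   n_fields = cs@nFields,
                   n_total = unname(pooled[["total"]]),
                   n_low = unname(pooled[["low"]]),
                   n_high = unname(pooled[["high"]]),
                   grade_traditional = grade(gr$traditional),
                   grade_semiquantal = grade(gr$semiquantal),
                   valid = cs@valid,
                   validity_notes = cs@validityNotes))
}

.fmtIndex <- function(x) as.numeric(formatC(x, format = "f", digits = 1))
.fmtStat <- function(x) as.numeric(formatC(x, format = "f", digits = 3))
.fmtP <- function(x) as.numeric(formatC(x, format = "e", digits = 2))

.statJSON <- function(s) {
  if (is.character(s)) return(list(message = s))
  list(statistic = .fmtStat(s@statistic), df = s@df,
       p_value = .fmtP(s@pValue), method = s@method)
}

.curveJSON <- function(cv)
  list(times = cv@times, survival = cv@survival,
       at_risk = cv@atRisk, events = cv@events)

#' Run the cohort comparison from a CSV and serialize the report
#'
#' @param path cohort CSV path (see [readCohortCSV()] for the schema).
#' @param config configuration list; `dichotomize` selects the high/low
#'   split and `exclude_nec` drops rows flagged `nec_g3`.
#' @param out optional path for the JSON report.
#' @return the report list (as written), invisibly when `out` is given.
#' @export
runCohort <- function(path, config = defaultConfig(), out = NULL) {
  df <- readCohortCSV(path)
  if (isTRUE(config$exclude_nec) && "nec_g3" %in% names(df))
    df <- df[!as.logical(df$nec_g3), , drop = FALSE]
  if (!nrow(df)) stop("empty cohort after exclusions")
  rep <- cohortComparison(df, dichotomizeMethod = config$dichotomize,
                          g1Ceiling = config$g1_ceiling)
  mg <- rep$marginals
  json <- list(
    n = rep$n,
    reclassification = list(
      counts = unclass(counts(rep$reclassification)),
      traditional_percent = unname(mg$traditional),
      semiquantal_percent = unname(mg$semiquantal),
      traditional_cumulative = unname(mg$traditionalCumulative),
      semiquantal_cumulative = unname(mg$semiquantalCumulative)),
    chi_square = .statJSON(rep$chiSquare),
    correlations = lapply(rep$correlations, .statJSON),
    paired_t = .statJSON(rep$pairedT),
    survival = lapply(rep$survival, function(sv)
      list(n_high = sv$nHigh, n_low = sv$nLow,
           log_rank = .statJSON(sv$logRank),
           km_high = .curveJSON(sv$high), km_low = .curveJSON(sv$low))))
  if (!is.null(out)) {
    jsonlite::write_json(json, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep$json <- json
  rep
}
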