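#' Paired grade reclassification table
#'
#' Cross-tabulates each patient's WHO grade under the traditional index
#' (rows) against the semiquantal index (columns). Margins reproduce the
#' per-method grade distributions exactly.
#'
#' @param traditional,semiquantal grade vectors (values in G1/G2/G3), or
#'   pass a cohort data.frame as `traditional` with columns
#'   `grade_traditional` and `grade_semiquantal`.
#' @return a [ReclassTable].
#' @seealso [marginalPercents()]
#' @export
reclassification <- function(traditional, semiquantal = NULL) {
  if (is.data.frame(traditional)) {
    df <- traditional
    if (!all(c("grade_traditional", "grade_semiquantal") %in% names(df)))
      stop("cohort must have grade_traditional and grade_semiquantal columns")
    traditional <- df$grade_traditional
    semiquantal <- df$grade_semiquantal
  }
  if (!length(traditional))
    stop("empty cohort: nothing to cross-tabulate")
  if (length(traditional) != length(semiquantal))
    stop("grade vectors must have equal length")
  ft <- factor(as.character(traditional), levels = GRADE_LEVELS)
  fs <- factor(as.character(semiquantal), levels = GRADE_LEVELS)
  if (anyNA(ft) || anyNA(fs))
    stop("grades must be one of G1, G2, G3")
  cnt <- unclass(table(ft, fs))
  dimnames(cnt) <- list(traditional = GRADE_LEVELS,
                        semiquantal = GRADE_LEVELS)
  storage.mode(cnt) <- "integer"
  new("ReclassTable", counts = cnt, n = length(ft))
}

#' @describeIn reclassification marginal grade percentages (rounded to one
#'   decimal) and cumulative percentages for each method.
#' @param x a [ReclassTable].
#' @param ... unused.
#' @export
setMethod("marginalPercents", "ReclassTable", function(x, ...) {
  tp <- round(100 * rowSums(x@counts) / x@n, 1)
  sp <- round(100 * colSums(x@counts) / x@n, 1)
  list(traditional = tp, semiquantal = sp,
       traditionalCumulative = cumsum(tp),
       semiquantalCumulative = cumsum(sp))
})

.statResult <- function(statistic, df, pValue, method)
  new("StatResult", statistic = as.numeric(statistic), df = as.numeric(df),
      pValue = as.numeric(pValue), method = method)

#' Pearson chi-square test of independence
#'
#' Computed from the defining formula: expected counts from the row/column
#' margins, `X2 = sum((O - E)^2 / E)`, no continuity correction. Rows and
#' columns with zero margins are dropped before computing the degrees of
#' freedom `(r - 1)(c - 1)`.
#'
#' @param table a [ReclassTable] or a non-negative integer matrix.
#' @return a [StatResult] with the upper-tail chi-square p-value.
#' @export
chiSquare <- function(table) {
  O <- if (is(table, "ReclassTable")) table@counts else as.matrix(table)
  if (any(O < 0) || sum(O) <= 0)
    stop("table must be non-negative with positive total")
  O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
  if (nrow(O) < 2L || ncol(O) < 2L)
    stop("degenerate table: fewer than 2 non-empty rows or columns")
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  if (any(E == 0)) {
    bad <- which(E == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("degenerate table: expected count 0 in cell (%d, %d)",
                 bad[1], bad[2]))
  }
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  .statResult(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              "Pearson chi-square")
}

#' Pearson correlation with two-tailed t test
#'
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(...)`; significance via
#' `t = r sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @return a [StatResult]; `statistic` is r, `df` is n - 2.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx <= 0 || syy <= 0)
    stop("undefined correlation: zero variance")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  .statResult(r, n - 2, p, "Pearson correlation")
}

#' Paired t test
#'
#' On the differences `d = x - y`: `t = mean(d) / (sd(d) / sqrt(n))` with
#' n - 1 degrees of freedom, two-tailed. All-zero differences give t = 0,
#' p = 1; zero-variance differences with nonzero mean give an infinite
#' statistic (flagged in the method string) with p = 0.
#'
#' @param x,y equal-length numeric vectors, n >= 2.
#' @return a [StatResult].
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(.statResult(0, n - 1, 1, "paired t"))
    return(.statResult(sign(mean(d)) * Inf, n - 1, 0,
                       "paired t (zero-variance differences)"))
  }
  t <- mean(d) / (s / sqrt(n))
  .statResult(t, n - 1, 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
              "paired t")
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, where `d_i`
#' is the number of events at `t_i` and `n_i` the number at risk just
#' before. Subjects censored at an event time are still at risk at that
#' time (events precede censorings at ties).
#'
#' @param times follow-up times (>= 0).
#' @param events logical or 0/1 event indicators (TRUE = death observed).
#' @return a [SurvivalCurve].
#' @export
kmEstimate <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events must have equal length")
  if (anyNA(times) || any(times < 0)) stop("times must be >= 0")
  events <- as.logical(events)
  et <- sort(unique(times[events]))
  if (!length(et))
    return(new("SurvivalCurve", times = numeric(0), survival = numeric(0),
               atRisk = integer(0), events = integer(0)))
  nAtRisk <- vapply(et, function(t) sum(times >= t), numeric(1))
  d <- vapply(et, function(t) sum(events & times == t), numeric(1))
  s <- cumprod(1 - d / nAtRisk)
  new("SurvivalCurve", times = et, survival = s,
      atRisk = as.integer(nAtRisk), events = as.integer(d))
}

#' Two-group Mantel-Cox log-rank test
#'
#' At each distinct event time, the observed events in group A are compared
#' with the expectation under the hypergeometric null
#' (`E = d * nA / n`, variance `d (nA/n)(nB/n)(n - d)/(n - 1)`); the
#' statistic `(sum(O - E))^2 / sum(V)` is chi-square with 1 df.
#'
#' @param timesA,eventsA follow-up and event indicator of group A.
#' @param timesB,eventsB same for group B.
#' @return a [StatResult].
#' @export
logRank <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB))
    stop("both groups must be non-empty")
  eventsA <- as.logical(eventsA); eventsB <- as.logical(eventsB)
  if (anyNA(c(timesA, timesB)) || any(c(timesA, timesB) < 0))
    stop("times must be >= 0")
  allT <- c(timesA, timesB)
  allE <- c(eventsA, eventsB)
  et <- sort(unique(allT[allE]))
  if (!length(et))
    stop("undefined test: no events in either group")
  OmE <- 0; V <- 0
  for (t in et) {
    nA <- sum(timesA >= t); nB <- sum(timesB >= t)
    n <- nA + nB
    d <- sum(allE & allT == t)
    dA <- sum(eventsA & timesA == t)
    OmE <- OmE + dA - d * nA / n
    if (n > 1)
      V <- V + d * (nA / n) * (nB / n) * (n - d) / (n - 1)
  }
  if (V <= 0)
    return(.statResult(0, 1, 1, "Mantel-Cox log-rank"))
  stat <- OmE^2 / V
  .statResult(stat, 1, stats::pchisq(stat, 1, lower.tail = FALSE),
              "Mantel-Cox log-rank")
}

#' Split a cohort into high / low proliferation groups
#'
#' `grade_threshold` uses the G1/G2 clinical boundary: high means index
#' >= 3% (or mitotic count >= 2). `median` puts strictly-above-median cases
#' in the high group (ties to low).
#'
#' @param records cohort data.frame (see [readCohortCSV()] for the schema).
#' @param method `"grade_threshold"` or `"median"`.
#' @param measure `"traditional"`, `"semiquantal"` or `"mitoses"`.
#' @return list with logical vector `high`, the two subset data.frames
#'   `highGroup` / `lowGroup`, and `degenerate` (TRUE when either group is
#'   empty, with a warning).
#' @export
dichotomize <- function(records,
                        method = c("grade_threshold", "median"),
                        measure = c("traditional", "semiquantal", "mitoses")) {
  method <- match.arg(method)
  measure <- match.arg(measure)
  if (!nrow(records)) stop("empty cohort")
  v <- switch(measure,
              traditional = records$traditional_index,
              semiquantal = records$semiquantal_index,
              mitoses = records$mitotic_count)
  high <- if (method == "grade_threshold") {
    if (measure == "mitoses") v >= 2 else v >= 3
  } else {
    v > stats::median(v)
  }
  degenerate <- !any(high) || all(high)
  if (degenerate)
    warning("degenerate split: one group is empty")
  list(high = high,
       highGroup = records[high, , drop = FALSE],
       lowGroup = records[!high, , drop = FALSE],
       degenerate = degenerate)
}

#' Full cohort comparison report
#'
#' Runs the whole comparison battery on a cohort: grade reclassification
#' with chi-square, pairwise Pearson correlations among the three
#' proliferation measures, the paired t test of traditional vs semiquantal
#' index, and per-measure Kaplan-Meier curves with the Mantel-Cox log-rank
#' test on a high/low dichotomization of overall survival.
#'
#' @param records cohort data.frame; if grade columns are absent they are
#'   computed from the indices and mitotic counts via [combinedGrade()].
#' @param dichotomizeMethod passed to [dichotomize()].
#' @param g1Ceiling passed to [gradeFromKi67()].
#' @return a list: `reclassification` ([ReclassTable]), `marginals`,
#'   `chiSquare`, `correlations`, `pairedT`, and per-measure `survival`
#'   entries each holding the two [SurvivalCurve]s and the log-rank
#'   [StatResult] (or an explanatory message when a group is degenerate).
#' @export
cohortComparison <- function(records,
                             dichotomizeMethod = "grade_threshold",
                             g1Ceiling = 3) {
  if (!nrow(records)) stop("empty cohort")
  if (!"grade_traditional" %in% names(records)) {
    g <- combinedGrade(records$traditional_index, records$mitotic_count,
                       g1Ceiling = g1Ceiling)
    records$grade_traditional <- as.character(g$grade)
  }
  if (!"grade_semiquantal" %in% names(records)) {
    g <- combinedGrade(records$semiquantal_index, records$mitotic_count,
                       g1Ceiling = g1Ceiling)
    records$grade_semiquantal <- as.character(g$grade)
  }
  rt <- reclassification(records)
  chi <- tryCatch(chiSquare(rt), error = function(e) conditionMessage(e))
  corrs <- list(
    traditional_semiquantal = pearsonCorr(records$traditional_index,
                                          records$semiquantal_index),
    traditional_mitoses = pearsonCorr(records$traditional_index,
                                      records$mitotic_count),
    semiquantal_mitoses = pearsonCorr(records$semiquantal_index,
                                      records$mitotic_count))
  tt <- pairedT(records$traditional_index, records$semiquantal_index)
  surv <- lapply(c(traditional = "traditional", semiquantal = "semiquantal",
                   mitoses = "mitoses"), function(ms) {
    sp <- dichotomize(records, method = dichotomizeMethod, measure = ms)
    out <- list(
      high = kmEstimate(sp$highGroup$os_years, sp$highGroup$event),
      low = kmEstimate(sp$lowGroup$os_years, sp$lowGroup$event),
      nHigh = nrow(sp$highGroup), nLow = nrow(sp$lowGroup))
    out$logRank <- if (sp$degenerate)
      "log-rank not computed: degenerate high/low split"
    else tryCatch(
      logRank(sp$highGroup$os_years, sp$highGroup$event,
              sp$lowGroup$os_years, sp$lowGroup$event),
      error = function(e) conditionMessage(e))
    out
  })
  list(reclassification = rt, marginals = marginalPercents(rt),
       chiSquare = chi, correlations = corrs, pairedT = tt,
       survival = surv, n = nrow(records))
}
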