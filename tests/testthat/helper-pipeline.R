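# Shared fixtures and pipeline helpers built in code.

# Build a FieldScore directly from counts.
fsCounts <- function(total, low, high, id = "f") {
  new("FieldScore", fieldId = id, nTotal = as.integer(total),
      nNegative = as.integer(total - low - high), nLow = as.integer(low),
      nHigh = as.integer(high))
}

# Render one field from params and push it through the full pipeline,
# returning recovered counts plus the ground truth.
scoreRenderedField <- function(params) {
  rf <- renderField(params)
  od <- fieldToOD(rf$field)
  rec <- extractRecords(segmentNuclei(od), od)
  list(score = scoreField(rec, fieldId = fieldId(rf$field)),
       records = rec, truth = rf$truth)
}

# Score a synthetic case of nFields fields (seeds derived from caseSeed)
# and return recovered vs ground-truth indices.
scoreSyntheticCase <- function(caseSeed, nFields = 10L, nNuclei = 110L,
                               nStromal = 0L,
                               classProportions = c(0.80, 0.12, 0.08)) {
  scores <- vector("list", nFields)
  tTrad <- tSemi <- tN <- 0
  for (k in seq_len(nFields)) {
    p <- fieldSimParams(nTumorNuclei = nNuclei, nStromal = nStromal,
                        widthPx = if (nStromal > 0) 500L else 420L,
                        heightPx = if (nStromal > 0) 500L else 420L,
                        classProportions = classProportions,
                        seed = caseSeed * 100L + k)
    out <- scoreRenderedField(p)
    scores[[k]] <- out$score
    nT <- sum(out$truth$nuclei$class != "stromal")
    tTrad <- tTrad + nT * out$truth$traditionalIndex / 100
    tSemi <- tSemi + nT * out$truth$semiquantalIndex / 100
    tN <- tN + nT
  }
  cs <- scoreCase(scores, mitoticCount = 0L, caseId = sprintf("c%d", caseSeed))
  list(case = cs,
       truthTraditional = 100 * tTrad / tN,
       truthSemiquantal = 100 * tSemi / tN)
}

# Grade vectors realizing given per-grade marginal counts, paired
# monotonically (semiquantal never above traditional grade-wise).
gradesFromCounts <- function(cnt) rep(c("G1", "G2", "G3"), cnt)
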