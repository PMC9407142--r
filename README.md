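# semiKi67

Semiquantal Ki-67 scoring and WHO grading for gastro-entero-pancreatic
neuroendocrine tumors (GEP-NETs), with the cohort statistics needed to
compare it against conventional scoring.

## The problem and who this is for

The Ki-67 proliferation index drives the WHO G1/G2/G3 grading of GEP-NETs,
but the conventional rule — count every nucleus with *any* discernible DAB
staining — is sensitive to pale, weakly positive nuclei. Many of those are
biologically uninformative (Ki-67 is continuously degraded after mitosis, so
weak staining can reflect residual protein in resting cells) or are outright
false positives from proliferating stromal cells, which are typically
smaller and spindle-shaped. The *semiquantal* index instead counts only
nuclei with high-intensity (dark brown to black) staining, on the rationale
that these are the cells genuinely near G2/M.

This package is for pathology image analysts and biostatisticians who want a
transparent, scriptable implementation of both indices:

* **Stain separation.** RGB brightfield fields are converted to optical
  density (`OD_c = -log10((I_c + 1)/(i0 + 1))`) and unmixed with the
  standard H-DAB stain matrix (Beer–Lambert linearity), giving per-pixel
  hematoxylin and DAB concentration maps.
* **Nucleus segmentation.** Otsu thresholding of the smoothed total nuclear
  OD, distance-transform markers and a marker-controlled watershed; fully
  deterministic. Inclusion filters are physical: area within
  [20, 400] µm² and eccentricity < 0.95, which removes small
  spindle-shaped stromal nuclei.
* **Intensity classing.** Mean nuclear DAB OD below 0.15 is negative, up to
  0.60 is "low" (pale brown), at or above 0.60 is "high" (dark brown/black).
  Traditional index = 100 · (low + high)/total; semiquantal index =
  100 · high/total, pooled over ≥ 10 high-power fields.
* **WHO grading.** G1: Ki-67 < 3% or mitoses 0–1 /10 HPF; G2: 3–20% or
  2–20; G3: > 20% or > 20. The overall grade is the worse component.
* **Cohort statistics**, implemented from their defining formulas so every
  number is auditable: grade reclassification cross-tab with Pearson χ²,
  Pearson correlations, paired *t*, Kaplan–Meier product-limit curves and
  the Mantel–Cox log-rank test.
* **Synthetic generators** for H-DAB fields (with per-nucleus ground truth,
  including stromal confounders) and patient cohorts (grade-conditional
  log-normal indices, additive low-stain excess, grade-dependent survival),
  so the entire pipeline is testable end to end without patient data.

## Worked example

```r
library(semiKi67)

# a synthetic field: 120 tumour nuclei, 80% negative / 12% low / 8% high
rf   <- renderField(fieldSimParams(nTumorNuclei = 120L,
                                   classProportions = c(0.80, 0.12, 0.08),
                                   seed = 42L))
od   <- fieldToOD(rf$field)          # H-DAB deconvolution
mask <- segmentNuclei(od)            # deterministic watershed
rec  <- extractRecords(mask, od)     # per-nucleus geometry + mean ODs
scoreField(rec, fieldId = "demo-field")
#> FieldScore 'demo-field': 120 nuclei (neg 98, low 11, high 11)
```

The ground truth for this field is 17.5% traditional / 9.2% semiquantal;
the recovered field has 22/120 = 18.3% stained and 11/120 = 9.2% high.
Pooling ten such fields and grading:

```r
cs <- scoreCase(replicate(10, scoreField(rec), simplify = FALSE),
                mitoticCount = 3L, caseId = "demo")
cs
#> CaseScore 'demo': traditional 18.3%, semiquantal 9.2% over 10 field(s); mitoses 3 /10 HPF
gradeCase(cs)$traditional
#> WHO grade G2 (Ki-67 component G2, mitotic component G2)
```

Cohort-level comparison on a simulated 87-patient cohort:

```r
coh <- simulateCohort(cohortSimParams(seed = 1L))
rep <- cohortComparison(coh)
rep$reclassification
#> ReclassTable (n = 87): traditional grade (rows) vs semiquantal grade (cols)
#>            semiquantal
#> traditional G1 G2 G3
#>          G1  4  0  0
#>          G2 36 33  0
#>          G3  4  6  4
rep$pairedT
#> paired t: statistic = 8.065, df = 86, p = 3.914e-12
rep$survival$semiquantal$logRank
#> Mantel-Cox log-rank: statistic = 23.52, df = 1, p = 1.237e-06
```

Reading the table: 36 of 87 patients drop from G2 to G1 when only
high-intensity nuclei are counted — the semiquantal method never up-grades
(all mass on or below the diagonal), the traditional index is significantly
larger pair-wise, and the semiquantal high/low split separates overall
survival.

A command-line wrapper with subcommands `score-image`, `score-case`,
`grade`, `cohort-stats` and `simulate` ships in `inst/cli/semiKi67.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/semiKi67.R", package="semiKi67"))')" \
    score-image --image field.png --mpp 0.5
```

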