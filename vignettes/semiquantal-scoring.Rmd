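---
title: "Semiquantal Ki-67 scoring: models, parameters and design choices"
author: "semiKi67 maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiquantal Ki-67 scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiKi67)
```

## Why intensity matters

Ki-67 accumulates through the cell cycle, peaks at mitosis, and is
continuously degraded afterwards; a faintly stained nucleus may therefore be
a cell leaving the cycle rather than one proliferating. Weakly stained
non-tumour cells — proliferating stromal cells in particular, which are
smaller and spindle-shaped — add further false positives to a count that
accepts any discernible staining. The semiquantal index responds to both
problems at once: it counts only nuclei whose DAB staining is high-intensity
(dark brown to black), and the pipeline's geometric inclusion filters remove
stromal shapes before any counting happens.

This vignette records the models behind each stage, the tunable parameters
with their defaults and rationale, what the synthetic generators do and do
not emulate, and the design decisions taken where the problem was genuinely
open.

## Stain model

Brightfield absorbance is linear in stain concentration in optical-density
space (Beer–Lambert). Per channel,

$$OD_c = -\log_{10}\frac{I_c + 1}{i_0 + 1},$$

with $i_0$ the blank intensity (default 255; configurable for scanners with
grey backgrounds) and the $+1$ offset guarding $\log 0$ at pixel value 0.
A pixel's OD vector is modelled as a non-negative combination of unit stain
vectors — hematoxylin $(0.65, 0.70, 0.29)$ and DAB $(0.27, 0.57, 0.78)$,
the standard published H-DAB pair, completed by their normalized cross
product as a residual channel. `deconvolve()` inverts this 3×3 system
exactly per pixel and clips negative concentrations to zero (physical
non-negativity); `composeOD()` is the exact inverse used by the renderer,
followed by rounding to 8-bit intensities.

**Dynamic range.** The round trip compose → OD → deconvolve is limited only
by 8-bit quantization. Where the total chromogen load (hematoxylin + DAB
concentration) stays within 1.5, the maximum reconstruction error is
0.017 OD; tests assert ≤ 0.02 OD on a 0.05-step grid over that region. At
higher loads the transmitted light falls to a handful of counts per channel
(e.g. green intensity ≈ 2 at load 3), where a single quantization step is
worth ≈ 0.1 OD and no estimator can do better; nuclei rendered by the
generator (counterstain ≈ 0.45 plus DAB ≤ ≈ 1.0) stay inside the
well-conditioned region.

## Segmentation

The detection map is the total nuclear OD (hematoxylin + DAB), so negative
and strongly positive nuclei are found by the same route. The procedure is
Gaussian smoothing (σ = 0.5 µm), Otsu thresholding, hole filling, the
Euclidean distance transform, local maxima as markers, and a
marker-controlled watershed. Two numerical choices deserve a note:

* **Threshold on the compressed map.** Otsu's criterion splits the
  histogram where variance is largest; with a strongly bimodal *intensity*
  distribution inside the tissue (pale vs dark nuclei), a cut on the raw OD
  map can land between nucleus classes instead of between tissue and
  background, silently dropping the palest nuclei. The threshold is
  therefore computed on the square-root-compressed map, which shrinks
  intensity contrast within tissue while preserving the tissue/background
  step, and is never taken below the `minNuclearOD` noise floor
  (0.1 OD) — so a blank field yields no objects rather than thresholded
  noise.
* **Deterministic markers.** Local maxima of the distance map are collected
  at a minimum separation of 3 µm, visited in lexicographic (row, column)
  order with greedy acceptance; watershed regions are grown by geodesic
  propagation from those markers. Every step is deterministic, so a field
  segments to the bit-identical mask on every run.

Per-nucleus intensity is measured on the region's *morphological core* —
pixels farther than the smoothing radius from the outer foreground
boundary — because the smoothed threshold adds a pale halo around each
nucleus that would otherwise dilute its mean OD (by ≈ 20% for a 3.5 µm
nucleus); thin regions without core pixels fall back to all pixels.

### Inclusion filters

| parameter | default | unit | rationale |
|---|---|---|---|
| `minAreaUm2` | 20 | µm² | drops debris and fragments of thin stromal nuclei |
| `maxAreaUm2` | 400 | µm² | drops clumps the watershed failed to split |
| `maxEccentricity` | 0.95 | — | spindle filter: a 3:1 ellipse has ecc. 0.943, a 4:1 ellipse 0.968 |
| `smoothingSigmaUm` | 0.5 | µm | roughly the optical blur of a 40× brightfield system |
| `minPeakSeparationUm` | 3 | µm | below the smallest accepted nucleus diameter |

All thresholds are physical (µm, µm²) and converted through the image's
microns-per-pixel, so behaviour is magnification-independent. Size
violations take precedence over the spindle reason in the recorded
exclusion label. Whether a human observer's "do not count stromal cells"
rule acts on geometry, context or texture is unknowable from geometry
alone; here the exclusion is purely geometric, which the stromal-robustness
test shows is sufficient for spindle-shaped confounders of the modelled
kind.

## Intensity classes and indices

Mean nuclear DAB OD is classed as negative (< 0.15), low (0.15–0.60,
"pale brown") or high (≥ 0.60, "dark brown or black"). Both thresholds are
configuration keys, since no published numeric boundary exists for the
visual classes; the defaults were placed so that the renderer's pale class
(0.35 ± 0.05 OD) sits centrally between them and its dark class
(0.90 ± 0.05) is well above the upper cut. Boundary values belong to the
upper class — a deterministic, documented convention.

The case-level indices pool counts across fields (sum of numerators over
sum of denominators) rather than averaging per-field percentages: counting
is described over ≥ 10 fields as one tally, and pooling weights each field
by its cellularity, so a sparse field cannot dominate. The semiquantal
index is a sub-count of the traditional one, hence
`semiquantal ≤ traditional` holds for every case by construction — this
single inequality, pushed through monotone grade thresholds, is the
mechanism behind the systematic down-classification the method produces.

Cases with fewer than 10 fields or ≤ 100 nuclei are scored but flagged
invalid with explanatory notes, mirroring minimum-material inclusion rules
without refusing partial material. Zero nuclei across all fields is an
error: the indices are undefined, not zero.

## Grading

G1: Ki-67 < 3% or mitoses 0–1 per 10 HPF; G2: 3–20% or 2–20; G3: > 20% or
> 20. The printed convention for the bands leaves a gap between a G1
ceiling of 2% and a G2 floor of 3%; the package closes it at 3%
(`g1Ceiling`, configurable), the current WHO convention. The combined grade
is the maximum of the two component grades. The mitotic count is an input
measured on H&E sections, never computed from pixels.

## Cohort statistics

χ², Pearson r, the paired *t*, the Kaplan–Meier estimator and the
Mantel–Cox log-rank are implemented from their defining formulas rather
than delegated, so each has a small-fixture oracle test (and the suite
cross-checks them against `stats` and `survival`). Conventions: no
continuity correction in χ²; zero-margin rows/columns dropped before
computing df; events precede censorings at tied times in the product-limit
estimator; the log-rank variance is hypergeometric with the `n = 1` terms
skipped; p-values are two-tailed and reported at full precision, with the
α = 0.05 label applied only in summaries. Degenerate inputs are explicit:
zero-variance correlations and all-censored log-rank inputs are errors,
zero-variance paired differences with nonzero mean yield an infinite-t
flag, and a single-grade reclassification table produces an explanatory
message rather than a χ² value.

Survival comparisons dichotomize at the G1/G2 clinical boundary by default
(index ≥ 3%, or ≥ 2 mitoses) — the one clinically meaningful cut — with a
median split available; ties go to the low group. Records flagged as
poorly differentiated carcinomas (`nec_g3`) can be excluded with a config
switch; by default every supplied record is analysed.

## The synthetic generators

`renderField()` emulates what the scoring pipeline needs to see: disk-like
tumour nuclei with class-conditional DAB OD (0.02 / 0.35 / 0.90 ± 0.05),
shared hematoxylin counterstain (0.45 ± 0.05), spindle-shaped stromal
nuclei (axis ratio 5, semi-minor axis 1 µm, pale DAB 0.30 — deliberate
false positives), non-overlapping rejection-sampled placement, exact
composition to 8-bit RGB and mild Gaussian pixel noise (sd 2 on the 0–255
scale). Ground-truth indices are defined from tumour-nucleus class labels
only; stromal staining is a false positive by construction and never enters
the truth. All draws flow through named sub-streams of one seed, so adding
a draw to one stage cannot perturb another, and rendering is byte-identical
per seed.

It does **not** emulate chromatin texture, uneven illumination, stain
batch variation, overlapping nuclear clusters beyond the configurable
overlap fraction, or tissue architecture. Passing the end-to-end tests
therefore shows the pipeline's logic is correct under controlled imaging,
not that it is robust to every real-world artefact.

`simulateCohort()` generates 87-patient cohorts shaped like a GEP-NET
series: latent grade mixture (0.61, 0.30, 0.09), grade-conditional
log-normal semiquantal indices (log-normal because observed index
distributions have sd larger than the mean, i.e. strong right skew),
traditional = semiquantal + an independent log-normal excess (meanlog 1.35,
sdlog 0.9, giving a mean excess ≈ 5.8 points and r ≈ 0.7–0.9 between the
two indices), mitoses ~ Poisson(0.55 × semiquantal), exponential survival
with hazards (0.008, 0.06, 0.30) per year by latent grade, and uniform
administrative censoring over 1.6–9.5 years of follow-up. These defaults
were chosen once as a realistic calibration — cohort means land near 13
(traditional) and 6–8 (semiquantal) with ~80–90% of patients alive — and
are not fitted to any particular dataset. The disease-free interval is
generated independently of the proliferation measures (no correlation is
modelled, since none is expected to be detectable).

## Problem sizes in the test suite

The headline end-to-end test scores 20 rendered cases of 10 fields × 110
nuclei (≈ 22,000 nuclei) and requires index recovery within ±1.5
percentage points with the semiquantal ≤ traditional inequality everywhere;
stromal robustness adds 50% spindle confounders to 4 paired cases and
requires < 1 point of index shift; the log-rank null calibration uses 500
simulated cohorts of n = 87 and requires a rejection rate in [0.03, 0.07];
the G1-enrichment directionality property uses 200 cohorts. The acceptance
script repeats the same computations at 10 / 3 / 200 / 200 replicates.

## Known limitations

* Touching-nucleus resolution is watershed-grade: heavily clustered tissue
  will under-segment, which biases the denominator, not the intensity
  classes.
* The OD intensity scale is an engineering replacement for the proprietary
  intensity measurements of commercial packages; thresholds transfer only
  after calibration on one's own material.
* Stromal exclusion is geometric; stromal nuclei that are round and
  tumour-sized are indistinguishable here.
* No hotspot selection: fields are taken as supplied.
* No Cox regression or multivariable survival modelling; the survival
  machinery is deliberately limited to the two-group comparisons it
  implements exactly.
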