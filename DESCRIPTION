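Package: semiKi67
Title: Semiquantal Ki-67 Scoring and WHO Grading for Neuroendocrine Tumors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-image-analysis pipeline for Ki-67 immunohistochemistry
    in gastro-entero-pancreatic neuroendocrine tumors (GEP-NETs). Separates
    H-DAB brightfield fields into per-stain optical-density maps, segments
    nuclei with size and shape inclusion filters, classifies nuclear DAB
    intensity into negative/low/high, and computes both the traditional
    (any discernible staining) and the semiquantal (high-intensity only)
    Ki-67 proliferation indices with WHO G1/G2/G3 grading from Ki-67 index
    and mitotic count. Includes cohort-level comparison statistics
    (reclassification chi-square, Pearson correlations, paired t,
    Kaplan-Meier with Mantel-Cox log-rank) implemented from their defining
    formulas, and synthetic field-image and patient-cohort generators with
    per-nucleus ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
biocViews: CellBasedAssays, Classification, Survival, Pathology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
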