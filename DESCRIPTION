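Package: regularogram
Title: Irregular-Irregularity Indices, Regularograms, and Atrial
    Fibrillation Detection from RR Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies irregularly irregular heart rhythms from RR-interval
    series using iterated-difference (modified entropy scale, MESC) indices:
    per-window variability (distribution width), normality (closeness of the
    standardized MESC distribution to a Gaussian, via exact or fast binned
    Kolmogorov-Smirnov statistics) and mean RR.  Draws regularograms (RGG),
    2-D or 3-D scatter plots of the per-window indices in which atrial
    fibrillation occupies a characteristic high-variability/high-normality
    zone, and estimates AF burden from a marked rectangle.  Includes an
    explainable split-capped decision-tree AF detector with clinical
    performance metrics, record-level cross-validation for hyperparameter
    selection, patient-to-self and cross-cohort evaluation protocols, a
    seeded synthetic RR generator (AF, sinus rhythm, bigeminy, trigeminy,
    AV block, premature complexes) with ground-truth rhythm segments, and
    readers for PhysioNet-style beat and rhythm annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lattice,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart
Config/testthat/edition: 3
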