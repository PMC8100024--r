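Package: boneMorph
Title: Quantitative Histomorphometry and Micro-CT Morphometry of Osteoarthritic Knee Joints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative bone and cartilage morphometry in
    preclinical knee osteoarthritis studies. Implements zoned cartilage and
    subchondral plate thickness stereology and a surface fibrillation index on
    traced histological section profiles; 2D trabecular stereology (Tb.A and
    diagonal-intercept Tb.Th, Tb.Sp, Tb.N) on binary masks; 3D trabecular
    microarchitecture (BV/TV, maximal-sphere Tb.Th and Tb.Sp, plate-model
    Tb.N) in anatomically placed cylindrical volumes of interest; the
    group-comparison statistics used in such studies (Shapiro-Wilk and Levene
    gating, Student's t or Mann-Whitney, one-way ANOVA with Holm-Sidak or
    Kruskal-Wallis with Dunn post-hoc, 2D-3D Pearson correlation tables); and
    synthetic phantom and cohort generators with analytic ground truth so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    tiff,
    png,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
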