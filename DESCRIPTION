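Package: irecar
Title: Treatment Planning and Response Quantification for Irreversible
    Electroporation with Adoptive Cell Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing irreversible electroporation (IRE)
    tumor ablation studies combined with CAR T-cell therapy. Includes a
    finite-difference quasi-static electric field solver for two-needle and
    parallel-plate electrode configurations in heterogeneous tissue, lethal
    electric-field threshold calibration from hydrogel lesion measurements,
    Monte-Carlo tumor-coverage dose planning over voltage-to-distance ratios,
    longitudinal tumor-spheroid fluorescence quantification (segmentation,
    background-subtracted intensity, XTT normalization), caliper tumor-volume
    and survival analysis (Kaplan-Meier, pairwise log-rank with Bonferroni
    correction), and seeded synthetic-data generators that emulate each input
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    EBImage,
    yaml,
    tiff,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
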