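Package: leafScoreR
Title: Line-Scan Image Analysis and Trait Scoring for Rice Leaf Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for high-throughput rice leaf
    phenotyping with a tri-linear line-scan camera. Provides RGB channel
    re-registration, HSL colour-band segmentation with impurity removal,
    frame mosaicking that reconnects leaves cut at frame boundaries,
    per-leaf morphometrics (length, width, perimeter, area, compactness,
    green-colour classing), aggregation into 29 per-plant traits, accuracy
    statistics for method comparison, and post-GWAS summarisation
    (SNP filtering, Bonferroni thresholds from the effective marker
    number, 300-kb locus clumping with lead-SNP selection). A synthetic
    scan generator with analytic ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
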