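Package: fibremorph
Title: Automated Histomorphometry of Immunofluorescence Muscle Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated histomorphometry of fluorescently stained skeletal
    muscle cross-sections. Provides pre-processing of multi-channel
    immunofluorescence images (myosin slow, myosin fast, collagen),
    instance segmentation of muscle fibres, classification into slow, fast
    and hybrid fibre types, minimum Feret diameter morphometry, fibre type
    ratio and intramuscular collagen quantification, nerve cross-section
    morphometry (axon diameter, myelin thickness, overall diameter), and a
    statistical layer based on linear mixed models with Satterthwaite
    degrees of freedom, Benjamini-Hochberg false discovery control and
    Cohen's d effect sizes. A seeded synthetic-image generator produces
    tessellated muscle cross-sections and toy nerve sections with full
    ground truth, so the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
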