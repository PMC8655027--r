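Package: nucleostress
Title: Quantification of Nucleolar Stress and Nuclear Inclusions in
    Fluorescence Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-quantification and statistics pipeline for nucleolar
    stress phenotypes in multi-channel fluorescence microscopy. Segments
    DAPI-stained nuclei, classifies nucleolar marker signal (NPM1, NCL) as
    nucleolar or delocalized, measures nucleolar area per nucleus, detects
    intranuclear mutant-huntingtin inclusion bodies and computes the
    nucleoplasm/inclusion intensity dispersal ratio, then aggregates
    per-nucleus measurements to per-sample values for nonparametric group
    comparison (Mann-Whitney U, Kruskal-Wallis with Dunn's post hoc).
    Includes a synthetic microscopy generator with per-nucleus ground truth
    so every stage is testable by parameter recovery, plus relative qPCR
    expression (delta-delta-Ct) and disease-burden score helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'fieldspec.R'
    'imagefield.R'
    'inclusion.R'
    'io.R'
    'nucleolus.R'
    'nucleostress-package.R'
    'pipeline.R'
    'segment.R'
    'simulate.R'
    'stats.R'
    'utils.R'
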