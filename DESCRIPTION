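Package: FaceSym
Title: Reference-Free Facial Asymmetry Quantification from Paired Landmarks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies facial asymmetry in peripheral facial palsy from 2-D
    facial landmarks without a neutral reference image. Landmarks are aligned
    by an ordinary-least-squares facial midline fit and rigid rotation, signed
    angles of left-right landmark pairs against the horizontal form an
    asymmetry feature vector, and the mean absolute angle over a pair subset
    yields a global or region-wise asymmetry score in degrees. Informative
    pairs are selected by sweeping eta-squared effect-size thresholds against
    ordinal clinical grades (Stennert index) and maximizing Kruskal-Wallis
    separation; Spearman correlations relate scores to clinical severity.
    Includes a rotation-robustness protocol, privacy-preserving blue-to-red
    angle-map renderings (SVG), and a seeded synthetic cohort generator with
    grade-dependent, region-localized asymmetry for statistically controlled
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: BiomedicalInformatics, Visualization, FeatureExtraction,
    StatisticalMethod
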