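Package: hepaZone
Title: Zonal Hepatotoxicity Modelling in a 3D Hepatic Zonation Channel
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for a three-dimensional hepatic zonation
    channel in which a Wnt agonist (CHIR99021) diffuses along an agarose
    hydrogel channel and establishes a perivenous-like CYP expression
    gradient in HepaRG cells. Provides a one-dimensional Fickian gradient
    solver with a tangent-based linearity score and effective-diffusivity
    inversion, four-parameter-logistic dose-response fitting with IC50
    confidence intervals and log-scale IC50 shift tests, qPCR delta-delta-Ct
    quantification and a fold-change/P-value differential expression filter,
    ChemiDoc-style axial image profiling with membrane-damage fractions, and
    zone-resolved viability-surface prediction with a zonality classifier.
    A fully seeded synthetic-data generator reproduces the statistical
    structure of the wet-lab measurements so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Toxicology, DoseResponse, Regression, qPCR,
    DifferentialExpression
RoxygenNote: 7.3.3
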