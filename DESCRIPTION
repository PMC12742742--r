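Package: aletools
Title: Quantitative Analysis of Adaptive Laboratory Evolution Tolerance Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative workflow of adaptive
    laboratory evolution (ALE) studies of solvent tolerance in bacteria.
    Provides two-component-system (TCS) prioritization from population-level
    mutation data (frequency scores and regulon-weighted priority scores),
    promoter-fusion reporter quantification, post-search label-free
    proteomics filtering, imputation and differential gating, stress-response
    statistics (ROS induction, NPN outer-membrane permeability, survival
    fractions and their correlation), dilution spot-assay image
    quantification, and growth/fermentation kinetics including a
    four-parameter Gompertz production-rate fit. A seeded synthetic-data
    module emulates every input class with known ground truth so that the
    whole pipeline is testable without external files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    minpack.lm,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    limma,
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
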