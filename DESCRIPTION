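Package: growthdyn
Title: Longitudinal Growth Dynamics and Drought-Adaptation Analysis for
    High-Throughput Plant Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of daily image-derived plant traits from automated
    phenotyping platforms under control, nitrogen-, water- and combined
    stress. Provides growth-dynamics statistics (relative growth rate,
    coefficient-of-variation trajectories, water-use efficiency,
    stress-decline timing and magnitude), drought tolerance/recovery/
    adaptability indices with their inter-correlations, fuzzy c-means
    clustering of temporal biomass profiles with majority-rule selection
    of the cluster number, per-day mixed-model treatment testing with
    onset-of-significance detection, per-day REML variance-component
    decomposition, and maximum-likelihood fitting and BIC comparison of
    five repeated-measures covariance structures (uniform, power,
    heterogeneous power, first-order antedependence, unstructured).
    Includes a replicate-level synthetic trajectory generator emulating a
    multi-treatment greenhouse experiment, and a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    lme4,
    mclust,
    nlme,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
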