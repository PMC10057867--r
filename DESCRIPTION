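Package: pollenoptics
Title: Multi-Angle Light-Scattering Pollen Discrimination Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a four-channel optical
    particle counter used for automatic airborne-pollen monitoring. Provides a
    power-law intensity/diameter instrument model, a synthetic measurement
    session generator (lognormal grain-size distributions, channel gain
    factors per aerosol class, Poisson counting noise, contamination),
    local-outlier-factor frame filtering with silhouette-tuned parameters,
    oversampled cumulative size distributions, clustering-tendency testing
    (Hopkins statistic), hierarchical size clustering with validity-index
    voting, speciation-index optical signatures from histogram inversion, and
    per-size-cluster one-vs-one logistic classification with F1-optimised
    decision thresholds and repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
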