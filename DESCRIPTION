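Package: dermclone
Title: Clonal Dynamics and Fibroblast Division Estimation During Dermal Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of postnatal dermal maturation from
    lineage-tracing data. Provides a cylinder-body geometric estimator of the
    number of fibroblast divisions between two ages from body morphometry and
    per-layer cell densities, a seeded stochastic spatial simulator of tissue
    expansion with sparsely labelled clones (low division, negligible
    apoptosis), distance-cutoff clone calling with an exact minimum-clone
    partition, whole-mount quantification statistics (densities per dermal
    layer, marker-positive fractions, background-normalised fluorescence, new
    hair follicles per wound section), simulation-based parameter recovery,
    and synthetic-data generators that reproduce the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
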