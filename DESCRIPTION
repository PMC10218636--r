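Package: sretools
Title: Scale-Down Stimulus-Response Experiments in Anaerobic Chemostats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for scale-down stimulus-response
    experiments (SREs) in glucose-limited chemostats: a dynamic model of an
    intermittently fed anaerobic chemostat (Monod uptake kinetics, feed-off
    starvation pulses, carbon-mole balancing, ethanol stripping), estimation
    of uptake kinetics from feed-off depletion profiles, steady-state
    physiology tables (biomass-specific rates, C-mol yields, carbon
    recovery), and the downstream transcriptional-response statistics:
    negative-binomial GLM likelihood-ratio differential expression,
    expression-trajectory k-means clustering with hypergeometric functional
    enrichment, gene-set t-statistics, and exact multi-set intersection
    tests. Seeded synthetic-data generators emulate both the bioprocess
    measurements and impulse-shaped RNA-seq time courses so that every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    fgsea,
    mclust,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
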