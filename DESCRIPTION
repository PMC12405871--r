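Package: digenic
Title: Digenic Quantitative Genetics of Seed Dormancy, Germination, and
    Pericarp Flavonoids
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-locus (digenic) quantitative-genetic analysis of
    seed traits in rice, built around the red (Rc/rc) and purple (Pb/pb)
    pericarp-colour system. Computes germination percentage and the weighted
    germination index from daily count series, relative transcript abundance
    from qRT-PCR cycle thresholds, and seed water content from imbibition
    weight series. Encodes digenic genotypes into orthogonal additive,
    dominance, and epistatic contrasts; fits additive-dominance-epistasis
    models (with optional development-time interactions) by ordinary least
    squares with forward selection; and partitions phenotypic variance into
    per-term sequential R-squared components. Includes per-timepoint effect
    trajectories for imbibition time courses with three-phase piecewise-linear
    segmentation, moment-matched replicate reconstruction from published
    means and standard errors, and synthetic-data generators (F2 Mendelian
    segregation, germination count series, flavonoid panels, triphasic
    water-uptake curves) so every stage of the pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
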