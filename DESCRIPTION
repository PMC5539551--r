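Package: crustscreen
Title: Contamination Screening and Community Analysis for Low-Biomass
    16S rRNA Amplicon Surveys
Version: 0.9.0
Authors@R:
    person("Orcutt Lab", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening low-biomass 16S rRNA gene amplicon OTU
    tables against a sequenced background contamination control, as used in
    deep-biosphere (subseafloor sediment and basalt) surveys. Implements
    rare-OTU abundance filtering, four-bin provenance classification of
    OTUs relative to a control library (control-only, samples-only,
    sample-enriched, control:sample), microsphere-based sample exclusion
    rules, taxonomic aggregation and Jaccard community similarity on the
    screened table, qPCR gene-copy quantification with negative-control
    detection rules and cell-density conversion, and a seeded synthetic
    community generator (endemic, seawater, and reagent source pools) with
    ground-truth labels for validating the screen end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
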