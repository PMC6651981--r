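Package: bulkmark
Title: Bulk Sequence Analysis for Trait-Linked Marker Discovery in
    Mixed-Ploidy F1 Populations
Version: 0.1.0
Authors@R:
    person("bulkmark", "developers", email = "bulkmark@example.org",
           role = c("aut", "cre"))
Description: Tools for rapid identification of markers linked to a
    recessive trait locus from pooled genotyping-by-sequencing (GbS)
    data of a mixed-ploidy (diploid plus triploid) F1 population.
    Implements flow-cytometry based ploidy classification, pooled
    variant detection with coverage/count/frequency gates, single-bulk
    candidate contig selection (heterozygous in a diploid reference
    pool, near-fixed in a trait pool), segregation-ratio and
    co-segregation statistics, cultivar variant association, and a
    synthetic cross/GbS generator with unreduced-gamete (FDR/SDR/IMR)
    formation so every stage is testable without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
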