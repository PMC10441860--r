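Package: rhizonet
Title: Temporal Selection and Co-Occurrence Networks for Soil Microbiome
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for spatiotemporal analysis of soil
    bacterial communities under contrasting nitrogen fertilization:
    replicate-consensus OTU filtering and temporal specific-selection,
    Bray-Curtis dissimilarity with ANOSIM/PERMANOVA/PCoA, signed Spearman
    co-occurrence networks with FDR edge control and null-model topology
    comparison, keystone-taxon detection from within-module degree z and
    among-module participation c, inter-phylum negative-correlation
    accounting, phylum-gene redundancy analysis, and random-forest
    permutation importance linking selected taxa to nitrogen-cycling gene
    abundances. Includes a seeded synthetic-data generator emulating a
    5 treatment x 2 compartment x 5 stage x 6 replicate design with
    planted, recoverable structure for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
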