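Package: spongenet
Title: Modularity and Node Roles in Host-Microbiome Bipartite Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing host-microbiome bipartite
    occurrence networks, motivated by global sponge-microbiome surveys.
    Implements sample-selection, seawater-contaminant, core-microbiome and
    rarefaction filters for OTU count tables; Barber bipartite modularity
    with an LPAwb+-style label-propagation optimiser; within-module degree
    and participation-coefficient node-role profiling; unweighted UniFrac
    permutation tests of phylogenetic signal in network modules; one-factor
    PERMANOVA, dispersion homogeneity, PCoA, rank and indicator statistics
    for community tables; 16S copy-number-normalised predicted-metagenome
    aggregation; and a synthetic-data generator with planted modules for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
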