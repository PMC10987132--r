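Package: virocat
Title: Construction of Dereplicated, Annotated Gut Virome Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds a human gut virome catalogue from candidate contigs and
    detector evidence: multi-tool viral calling with a high-quality rescue
    rule, bacterial decontamination against prophage-masked references,
    terminal-repeat and junction-read circularity detection, greedy 95%
    average-nucleotide-identity dereplication into vOTUs, assembly-source
    group attribution, merged-region ANI novelty classification against
    reference catalogues, Markov clustering of the filtered genome homology
    graph into viral clusters, presence/prevalence/RPKM abundance and
    diversity statistics, crAssphage and Gubaphage identification, lifestyle
    binning with virulent-to-temperate ratios, COG-category enrichment, and
    CRISPR-spacer/tRNA virus-host assignment with LCA host ranges. Includes
    a fully deterministic synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    S4Vectors,
    Biostrings,
    IRanges,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
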