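Package: editome
Title: Detection and Analysis of RNA Editing in Haploid Genomes from
    RNA-Seq Pileups
Version: 0.1.0
Authors@R:
    person("Editome", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies RNA-editing sites in a haploid nuclear genome from
    per-site RNA-seq base counts using a binomial sequencing-error model with
    Benjamini-Hochberg correction, applies a cascade of artefact filters
    (edit-frequency bounds, sequence-context uniqueness, read strand bias,
    intron-edge proximity and DNA-seq concordance), characterises the spatial
    distribution of edits within genes (positional histograms, 5'-end
    enrichment, Monte-Carlo neighbour-distance clustering test), tests genes
    for condition-specific differential editing with per-gene binomial GLMs,
    classifies variant effects against gene models, prepares sequence-context
    sets for motif discovery, and ships a synthetic-data generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
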