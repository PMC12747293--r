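Package: selscape
Title: Genome-Wide Selection Landscape Analysis for Prokaryotic Lineages
Version: 0.1.0
Authors@R:
    person("Selscape", "Developers", email = "selscape@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogeny-aware analysis of selective constraints
    across prokaryotic lineages and gene families: maximum-likelihood dN/dS
    and transition/transversion estimation under a Goldman-Yang style codon
    model with mutation-count retention filters, additive decomposition of
    log dN/dS matrices into lineage-specific and gene-specific constraints
    by iterative backfitting with outlier removal, identification of
    splittable lineages and subtree heterogeneity testing, gene gain/loss
    flux estimation from ancestral presence/absence states, and a
    correlation layer with BCa bootstrap confidence intervals, subsampling
    nulls, and phylogeny-mapped correlations. Includes synthetic-data
    generators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
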