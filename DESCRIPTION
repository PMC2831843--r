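Package: htract
Title: Homopolymeric Tract Census and Positional Bias in Prokaryotic Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects maximal mononucleotide runs (homopolymeric tracts, HTs) in
    coding-gene sequences and tests their over- or under-representation against
    a composition-based binomial null model via Z-scores. Quantifies the 5'
    positional bias of tracts, codons and amino-acid residues with Wilcoxon
    rank-sum tests against uniform pseudo-null placements and first-10%
    odds-ratio enrichment with Fisher's exact test. Estimates frameshift
    reversion frequencies from selective-plating experiments (cell densities,
    dilution factors, colony-size classification, sequencing confirmation).
    Includes synthetic generators for composition-matched null gene sets, gene
    sets with planted tracts at controlled within-gene positions, and simulated
    plating experiments, so every stage of the pipeline can be validated
    without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
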