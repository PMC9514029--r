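Package: ervscreen
Title: In Silico Screen for Conserved Endogenous Retrovirus-Derived Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting evolutionarily conserved,
    domesticated endogenous retrovirus (ERV)-derived genes in a pair of
    related genomes. Harvests stop-flanked open reading frames from all six
    frames, scans their translations against retroviral protein-domain
    profile hidden Markov models with calibrated E-values, removes young
    ERV families by greedy identity clustering, pairs orthologous ORFs
    across species by local protein alignment, tests lineage specificity
    via query-cover and marker-gene proximity in outgroup genomes, and
    characterises surviving candidates with Nei-Gojobori dN/dS estimates,
    the codon-based Z-test of neutrality, neighbor-joining trees of the
    reverse-transcriptase region, and k-mer self-dotplots of the candidate
    locus. Ships a seeded synthetic two-species genome generator with a
    machine-readable truth table so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    ape,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
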