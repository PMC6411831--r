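Package: pingpongr
Title: Simulation and Analysis of piRNA Ping-Pong Signatures, Small-RNA
    Differential Abundance, Interactome Enrichment and Domain Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of PIWI-interacting RNA
    (piRNA) populations in arbovirus-infected mosquito cells and of the
    protein machinery that produces them. Provides a synthetic small-RNA
    read simulator with planted ping-pong structure (10-nt 5' overlaps,
    1U/10A nucleotide biases, knockdown effect sizes, hotspot windows),
    read collapsing and exact/one-mismatch placement on reference
    sequences, ping-pong diagnostics (positional nucleotide bias,
    5'-overlap probability with z-score, hotspot localisation,
    IP-versus-input enrichment), miRNA-normalised replicate comparisons
    with t-tests, label-free-quantification interactome enrichment with
    left-censored imputation and permutation-based FDR, neighbor-joining
    trees with bootstrap supports and reciprocal-nearest-neighbor
    ortholog calling for protein-domain alignments, and
    coefficient-of-variation scoring of fluorescence-signal granularity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
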