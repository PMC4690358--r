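Package: cubkit
Title: Codon Usage Bias Statistics and Comparative Analysis for
    Multi-Species Coding Sequence Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes synonymous codon usage statistics for sets of
    in-frame coding sequences: codon frequencies, GC content by codon
    position, relative synonymous codon usage (RSCU), Wright's effective
    number of codons (ENC) per gene and per species, per-amino-acid
    scaled ENC (sENC-x), and the codon adaptation index (CAI) with an
    expression-defined reference gene set.  Provides quality filters for
    ortholog-based multi-species datasets, hierarchical clustering of
    species on RSCU profiles with Newick export, correlation and
    regression analyses relating codon usage to GC3, gene expression and
    protein length, and a seeded simulator of multi-species CDS cohorts
    with controllable mutational bias and translational selection for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
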