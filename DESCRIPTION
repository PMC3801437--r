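Package: isremotif
Title: Interferon-Stimulated Gene Classification and ISRE Motif Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for partitioning interferon-stimulated genes into
    U-ISGF3-induced and classical ISGF3-only sets from bead-array expression data
    (quantile normalization, replicate-averaged fold-change and signal filters,
    gene-set algebra) and for testing whether the two sets' promoter interferon-
    stimulated response elements (ISREs) differ. Provides position-matrix parsing
    (JASPAR, TRANSFAC, MEME text dialects), log-likelihood-ratio PWM scanning of
    promoter windows, a CLOVER-style set-enrichment score with a shuffled-sequence
    null, flank-extended binding-site collection, position frequency matrix
    construction, sequence-logo information content, k-means clustering of
    one-hot-encoded sites, and a symmetrized position-averaged Kullback-Leibler
    motif divergence with label-permutation significance. A synthetic-data module
    generates expression matrices and promoter sequences with planted truth so
    every stage is testable end-to-end, plus small qPCR/ChIP/plaque-assay
    quantification helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    cluster,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
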