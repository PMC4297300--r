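Package: motifquant
Title: Quantitative Immunopeptidome Analysis and MHC Class II Binding-Motif Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free quantitative analysis of MHC class II
    immunopeptidomes: scale-ratio normalization of ion peak volumes from
    MaxQuant-style peptide tables, replicate averaging and abundance-share
    summaries, nested-set assignment and CLIP annotation, hierarchical
    clustering of repertoires, SAM-style permutation statistics with
    Grenander-based estimation of the proportion of truly differential
    peptides, and NNAlign-style neural-network discovery of 9-mer binding
    cores from variable-length peptides weighted by quantitative abundance,
    with position-specific scoring matrices and Shannon-logo output. A
    synthetic repertoire generator with planted binding motifs supports
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
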