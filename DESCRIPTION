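Package: epitopescan
Title: Epitope Discovery and Biomarker Panels for Phage-Display Immunoprofiling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of next-generation phage-display immunoprofiles
    (mimotope variation analysis): cleaning and read-count normalization of
    per-sample 12-mer peptide count tables, exhaustive discriminative
    discovery of fixed-residue epitope patterns scored by fold enrichment
    and hypergeometric p-values, alignment of patterns to linear epitopes
    and antigen protein sequences, immunoprofile similarity and
    immunodominance metrics (cosine similarity of top peptide profiles,
    per-patient Z-score maps, pre/post abundance ratios), and biomarker
    selection by Youden-optimal ROC cutoffs with combined logistic models.
    A synthetic-cohort generator with planted motifs and ground-truth
    tables supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
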