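Package: airrchimera
Title: Hidden Markov Model Detection of PCR Chimeras in Immune
    Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects PCR-generated chimeric V(D)J sequences in adaptive
    immune receptor repertoire (AIRR-seq) data. Queries annotated in the
    AIRR Rearrangement format are threaded onto a multiple sequence
    alignment of germline V (or J) alleles and scored with a
    duplicated-state hidden Markov model whose Forward posterior gives
    the probability that a sequence is a template-switched hybrid of two
    or more germline alleles; Viterbi decoding reports parent alleles
    and breakpoint columns. Somatic hypermutation is handled either by a
    grid of discretized mutation-rate states or by Baum-Welch
    re-estimation of a continuous per-reference rate. Includes a
    repertoire simulator with ground-truth chimera labels, a synthetic
    germline-set generator, and ROC/confusion evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
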