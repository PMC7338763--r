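Package: c4recruit
Title: Comparative Signatures of Gene Recruitment into C4 Photosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing how a C3 housekeeping gene is recruited
    into C4 photosynthesis, modeled on the phosphoenolpyruvate/phosphate
    translocator (PPT) paralog pair in Flaveria. Detects consistent C3-to-C4
    amino-acid modifications in ortholog alignments and maps their origin on a
    species tree by Fitch parsimony; characterizes lineage-specific tandem-repeat
    insertions together with slipped-strand-mispairing evidence (flanking direct
    repeats, Nussinov hairpin capability); scans promoters for cis-element
    submodules such as the MEM1 B core; quantifies expression-pattern shifts
    (tissue and cell-type dominance switches, qRT-PCR relative abundance,
    stepwise light-response tests); and runs a branch-site codon-model
    positive-selection likelihood-ratio test with Benjamini-Hochberg correction.
    A synthetic-data module generates every input the pipeline consumes, with
    planted truth tables, so all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
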