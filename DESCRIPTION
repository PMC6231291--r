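Package: tcrrecon
Title: Quantitative T Cell Receptor Repertoire Analysis for Immune
    Reconstitution Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of T cell receptor (TCR)
    repertoires during immune reconstitution after haematopoietic stem cell
    transplantation. Computes clonotype diversity (Gini coefficient of the
    clone-size Lorenz curve and Shannon entropy in bits), determines a
    minimum representative subsampling depth per sample from replicate
    rarefaction of the normalized Gini coefficient and optimizes a common
    depth across a cohort, reconstructs virtual CDR3-length spectratypes per
    TRBV family with Gaussian-shape scoring and three-group clinical
    classification, tracks abundant clonotypes longitudinally, annotates
    repertoires against VDJdb-format tables to summarize per-species antigen
    binding potential, and simulates synthetic repertoires and longitudinal
    reconstitution cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
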