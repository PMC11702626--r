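Package: crossphos
Title: Cross-Species Conservation Screening of Phosphosite Antibody Epitopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which phospho-specific antibodies raised against one
    species' proteins are likely to cross-react with orthologous proteins in
    another species. Given a phosphosite catalog with +/-7-residue flanking
    peptides, source and target proteomes, and a ranked ortholog-pair table,
    the pipeline anchors each catalog site on a current protein sequence
    (rescuing outdated accessions via gene symbol), maps genes to orthologs
    under a confidence-rank filter, computes affine-gap global protein
    alignments against every target isoform, and scores conservation of all
    6-11 residue windows spanning the phosphosite under strict identity and a
    one-conservative-substitution relaxation, alongside the contiguous
    identical run length through the site. Includes a synthetic-bundle
    generator with planted conservation outcomes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
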