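Package: crisprcensus
Title: Assembly, Classification and Census of CRISPR-Cas Genomic Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the identification, classification and census of
    CRISPR-Cas systems in prokaryotic genomes. Assembles CRISPR-cas loci
    from profile-hit annotations of protein-coding genes, classifies them
    against a versioned registry of the two-class, seven-type, 46-subtype
    taxonomy, builds profile-similarity UPGMA and hybrid dendrograms with
    an iterative constrained profile-merge loop, estimates adaptation and
    effector module shuffling from strict and permissive protein clusters,
    and computes phylogenetically weighted prevalence statistics that
    correct for uneven genome sampling. A synthetic-data generator with
    planted ground truth emulates every input format so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
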