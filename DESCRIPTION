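Package: oncocohort
Title: Simulation and Cohort Genomics of Somatic Copy Number, Mutational
    Signatures, and Gain Timing in Pediatric Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-scale somatic genomics of pediatric solid
    tumors, centred on neuroblastoma-style whole-genome data. Implements
    rule-based calling of segmental arm-level copy gains and losses,
    11q13.3 gains, whole-chromosome gains and the 9+ whole-chromosome
    class, and focal amplifications from absolute copy-number segment
    profiles; single-sample refitting of known trinucleotide mutational
    signatures with reconstruction quality control and per-mutation
    signature attribution probabilities; a purity-adjusted variant
    allele fraction model for classifying allele multiplicity and
    timing copy gains relative to point mutagenesis; structural-variant
    breakpoint linkage of copy alterations for independence-aware
    mutual-exclusivity testing; and age-group association statistics.
    A synthetic tumor-cohort generator with full ground truth makes
    every stage testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
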