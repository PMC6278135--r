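Package: epnmethyl
Title: Methylation-Based Molecular Classification of Posterior Fossa Ependymoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-methylation-based molecular classification of
    posterior fossa ependymoma into the PFA and PFB subgroups. Implements
    CpG-island probe selection on 450K-style beta-value matrices, two-group
    unsupervised hierarchical clustering, copy-number profiles derived from
    methylation-array intensities with arm-level gain calls (1q gain) and a
    chromosome-instability flag, a three-gene (CRIP1, DRD4, LBX2)
    beta-distribution likelihood-ratio classifier with rule-candidate
    selection on a stratified 1:2 train/validation split, and the H3K27me3
    immunohistochemistry cutoff rule. A seeded synthetic-cohort generator
    emulating a 450K-like array makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
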