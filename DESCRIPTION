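Package: onsetmod
Title: Modifier-Locus Analysis for Age at Onset in Multiplex Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An extreme-phenotype pipeline for detecting modifier loci that
    shift the age at onset (AAO) of a familial disease without altering
    susceptibility.  Families with two or more affected siblings are ranked by
    mean sibling AAO, probands from the two tails are contrasted in a
    covariate-adjusted logistic genome scan, and suggestive hits are carried
    through sibling replication, a four-group ordinal trend test, a
    log-odds-weighted multi-SNP genetic risk score, family-based (FBAT-style)
    association and frequency-matched case-control analysis.  Includes
    genotype/pedigree I/O (PED/MAP, minimal VCF), GWAS quality control
    (call rate, MAF, exact Hardy-Weinberg, KING-robust kinship, IBS/MDS
    stratification, genomic inflation), an analytic power calculator for the
    two-group design, and a seeded synthetic-cohort generator used as the
    test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
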