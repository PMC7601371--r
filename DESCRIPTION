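Package: echagg
Title: Familial Aggregation Analysis of Endemic Congenital Hypothyroidism
    in Pedigree Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing familial aggregation of a binary phenotype in
    pedigree-structured cohorts, motivated by historical survey data on
    endemic congenital hypothyroidism in severely iodine-deficient
    populations. Provides pedigree input/output in the 6-column PED dialect
    with a phenotype sidecar, Malecot kinship coefficients, nuclear-family
    decomposition, five aggregation tests (per-family binomial probability,
    kinship sum, genealogical index of familiality at cohort and family
    level, and probability of familial clustering) with Monte-Carlo null
    distributions and Benjamini-Hochberg correction, sibship-level
    chi-squared analysis against random case allocation, recessive-model
    probabilities, prevalence-scenario sweeps, synthetic cohort generators
    (independent, beta-binomial and Mendelian recessive mechanisms), and a
    deterministic reconstruction of a 62-family / 468-subject survey cohort
    from its published summary counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
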