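Package: hetfit
Title: Heterozygosity-Fitness Correlation Analysis for Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting inbreeding depression from codominant
    microsatellite genotypes and individual fitness records. Provides a
    genotype-table data model with GenAlEx-style two-column CSV input and
    output, per-locus diversity statistics (allelic richness, observed and
    unbiased expected heterozygosity, multi-allelic Hardy-Weinberg exact
    tests, Nei F_IS by cohort, Brookfield null-allele frequencies),
    per-individual multilocus heterozygosity indices (internal relatedness,
    standardized multilocus heterozygosity, heterozygosity-by-loci), the g2
    identity-disequilibrium statistic with bootstrap standard errors and
    permutation p-values, binomial heterozygosity-fitness models with
    Gelman standardization and information-theoretic conditional model
    averaging, a locus-by-locus AIC framework for distinguishing local from
    general (genome-wide) effects, and a synthetic-data generator with known
    individual inbreeding coefficients for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
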