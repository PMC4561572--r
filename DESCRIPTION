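Package: hybridtrace
Title: Hybrid Detection and Clinal Introgression Analysis for Two-Taxon
    Microsatellite Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diploid multilocus microsatellite surveys of
    two hybridizing sibling taxa sampled at paired field sites. Provides
    readers and writers for Genepop and STRUCTURE text formats; allele
    frequencies, heterozygosity and inbreeding coefficients; Nei (1972)
    standard genetic distances with neighbor-joining trees and a
    locus-resampling bootstrap; a supervised Bayesian genotype-class
    classifier (pure, migrant, F1, backcross) with per-generation
    hybridization and migration rate estimators; a permutation-calibrated
    test for clinal convergence of allele frequencies toward a focal site,
    plus Mantel and partial Mantel tests; private-allele accounting with a
    chi-squared proportion test and rare-shared-allele null expectations;
    and a Balding-Nichols simulator of two-taxon paired-site datasets with
    planted hybrids for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    geosphere,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
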