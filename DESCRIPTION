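Package: likertdim
Title: Monte Carlo Assessment of Over-Dimensionalisation in Factor Analysis of Likert Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates truly unidimensional five-category Likert item sets from
    four latent population distributions with a discretised ordinal error
    process, and assesses how often common factor-analytic procedures diagnose
    more than one dimension. Implements Pearson and two-step maximum-likelihood
    polychoric correlation estimation, eigenvalue-based factor-retention rules
    (Kaiser's K1, parallel analysis at the 95th centile, the acceleration
    factor), minimum-residual exploratory factor analysis with Bartlett-corrected
    chi-square, RMSEA, and nested-model difference tests, a 1-factor
    maximum-likelihood confirmatory model with GFI/AGFI, a grid runner that
    harvests per-dataset verdicts into risk tables, and OLS regressions of the
    fit statistics on item-set characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
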