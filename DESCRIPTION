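Package: fgmdr
Title: Fuzzy Generalized Multifactor Dimensionality Reduction for
    Gene-Gene Interaction Detection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects gene-gene interactions (epistasis) in SNP data by
    multifactor dimensionality reduction over score residuals from a null
    generalized linear model, with covariate adjustment for both binary
    and continuous traits.  Genotype cells of a k-SNP combination are
    graded into high- and low-risk groups by a fuzzy sigmoid membership
    function, and combinations are ranked by a fuzzy balanced accuracy
    under 10-fold cross-validation with cross-validation consistency.
    The crisp special cases reproduce MDR and GMDR.  Includes a
    penetrance-model simulator (marginal-effect-free two-locus models
    under Hardy-Weinberg equilibrium) and power evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
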