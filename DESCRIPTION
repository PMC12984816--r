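Package: qgped
Title: Pedigree-Based Genetic Parameter Estimation for Nested Aquaculture
    Breeding Designs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetic analysis of pedigreed aquaculture
    populations. Builds numerator relationship matrices and their sparse
    inverses from pedigrees, estimates variance components for univariate
    and multivariate linear animal models by restricted maximum likelihood
    (EM warm-up with average-information acceleration), fits an ordinal
    probit threshold sire-dam model by Gibbs sampling for categorical
    traits on the liability scale, and turns fitted components into
    heritabilities, common-environment fractions and genetic/phenotypic
    correlations with standard errors. Includes a calibrated simulator of
    nested full-sib/half-sib mating designs (sire x dam factorials with
    dam reuse, ordinal scores, stratified dissection subsamples,
    mortality and tag-loss missingness) so every estimator can be checked
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
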