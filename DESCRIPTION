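Package: linkscore
Title: Link-Function Weighted Association Tests and Genetic Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Score tests for case-control genetic association that remain
    efficient when disease risk does not combine multiplicatively on the odds
    scale. A generalized linear model link function assumed to hold at the
    population level induces stratum weights for stratified and marginal
    (Cochran-Armitage type) trend tests; the package provides these weighted
    tests with exact permutation variances, maximum-likelihood fitting of
    binomial regressions with power-odds (Box-Cox odds) links including profile
    likelihood for the link exponent, asymptotic non-centrality and relative
    efficiency calculations under link misspecification, and
    heritability-to-predictability computations (sibling recurrence risk ratio
    and ROC curves) under multiplicative, independent-sufficient-causes,
    quadratic-log and liability-threshold risk models, together with seeded
    simulators for stratified case-control studies and sibling pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
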