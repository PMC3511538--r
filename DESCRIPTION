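Package: beliefmine
Title: Evidential Diagnosis Ranking for Rare Disorders from Sparse Phenotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for rare-disorder diagnosis from sparse patient
    case collections. Mines probabilistic association rules (phenotype set ->
    disorder) with a level-wise frequent-itemset search, converts rule
    confidences into Dempster-Shafer basic belief assignments, combines the
    applicable evidence with Dempster's rule of combination, and ranks
    candidate disorders by a constrained belief function. Includes a
    stratified cross-validation harness with accuracy and macro
    precision/recall, a Laplace-smoothed Bernoulli naive Bayes baseline, and
    a synthetic case generator that emulates the rareness, sparseness and
    high dimensionality of real skeletal-dysplasia registries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
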