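Package: gacog
Title: Genetic-Algorithm Selection of Neuropsychological Test Subsets for
    Dementia Conversion Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wrapper feature selection over a 37-measure neuropsychological
    and mood test battery for modelling 36-month conversion from healthy
    cognition to mild cognitive impairment (MCI) or Alzheimer's disease (AD),
    and from MCI to AD.  A genetic algorithm evolves binary feature subsets
    under tournament selection, two-point crossover, single-bit mutation and
    elitism, scoring each subset by the cross-validated AUC of a logistic
    regression model penalised for subset size.  Includes a synthetic-cohort
    simulator with published per-group feature means, repeated balanced
    stratified k-fold and Monte-Carlo cross-validation, a backward-AIC
    stepwise baseline, random-subset baselines, and full-data model reports
    with Wald tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
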