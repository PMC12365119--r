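Package: peerbayes
Title: Bayesian Models of Social Information Use Under Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how people revise numerical estimates after
    seeing a peer's estimate and confidence rating. Implements a family of
    Bayesian evidence-fusion models in which personal and social evidence are
    represented as beta pseudo-counts, with precision modulators for own
    certainty and peer confidence and a confidence-dependent stay-bias mixture;
    per-participant maximum-likelihood fitting (grid search plus bounded
    quasi-Newton optimization) with BIC model comparison; the model-free
    social-information-use metric with trial and participant exclusion rules;
    model- and parameter-recovery diagnostics; and a seeded synthetic-cohort
    generator emulating the two-alternative proportion-estimation task so the
    full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
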