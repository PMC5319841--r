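Package: vectorsdm
Title: Bias-Matched Species Distribution Mapping for Malaria Vector Sibling Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline for mapping the geographical
    distributions of sibling species of African malaria vectors from
    presence/background occurrence records. Implements weighted boosted
    regression trees (stagewise Bernoulli-deviance boosting with shrinkage
    and bagging, written from scratch in C++), sampling-bias-matched
    background data with two detection-capability classes, desert
    pseudo-absences, range buffering and extension, a bootstrap ensemble of
    submodels summarised to per-pixel mean/median/quantile maps, and
    location-withheld AUC validation. Also provides curation and
    summarisation of insecticide-resistance bioassay records (molecular-ID
    and species-purity filtering, period binning, species-by-class
    summaries), and a seeded synthetic-world generator with known ground
    truth so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    mgcv,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
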