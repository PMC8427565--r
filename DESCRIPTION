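Package: caribouforage
Title: Summer Forage Selection Analysis for Arctic Caribou
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing summer forage selection by
    barren-ground caribou from GPS telemetry and weekly gridded forage
    predictions. Implements mosquito and oestrid-fly activity indices from
    temperature and wind, use-availability sampling against a minimum convex
    polygon, step construction with period-specific gamma step-length kernels,
    mixed-effects logistic resource selection functions fitted by adaptive
    Gauss-Hermite quadrature, conditional-logistic step selection with
    animal-year cluster-robust errors, AIC/QIC candidate-set selection,
    k-fold binned-Spearman cross-validation, and insect-driven movement-rate
    models. A synthetic-data module generates landscapes, weather, and
    telemetry with known ground truth so every stage is testable without
    restricted location data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
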