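Package: landsuit
Title: Climate-and-Soil Niche Models of Human Landuse with Shared-Suitability Conflict Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-only maximum-entropy (Gibbs) suitability modelling of
    landuse types on raster covariate stacks, an index of shared suitability
    (ISS) for mapping potential landuse conflict, deviation maps against a
    reference classification, and spatially corrected regressions linking
    suitability to population density, wealth, and conflict occurrence
    (Dutilleul's adjusted-degrees-of-freedom correlation test, Moran
    eigenvector spatial filtering, and breakpoint regression). Includes a
    synthetic-landscape generator with known ground truth for
    parameter-recovery experiments, ESRI ASCII grid input/output, and a
    reproducible end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    pROC,
    jsonlite
Config/testthat/edition: 3
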