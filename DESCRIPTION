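Package: ecohealth
Title: Ecosystem Health Assessment with the Pressure-State-Response Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for county-level ecosystem health assessment of land-use
    change scenarios such as the Grain for Green Program. Implements land-use
    transfer matrices and the land-cover change direction model (LCDM),
    sequential Mann-Kendall turning-point detection for annual NDVI series,
    landscape structure indices (fragmentation, Shannon diversity, average
    patch area, ecological resilience), an NPP-adjusted ecosystem-service
    valuation, analytic-hierarchy-process weight elicitation with Monte Carlo
    stabilisation, and composition of a weighted ecosystem health index (EHI)
    with a restored-area response regression. A synthetic-scenario generator
    provides gridded land-use series, bimonthly NDVI stacks, climate surfaces
    and county tables so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
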