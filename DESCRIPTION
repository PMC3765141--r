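Package: palmrisk
Title: Risk Mapping for Sustainable Oil Palm Expansion on Degraded Land
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit identification of low-risk ("degraded") land
    for sustainable oil palm expansion. Encodes sustainability-standard
    suitability thresholds (RSPO/RSB/RES-D aligned) as per-indicator rule
    tables, classifies raster indicator layers into four ordinal risk classes,
    builds composite High Conservation Value layers (protected-area buffers,
    large forest blocks, species habitat tiers), combines indicator layers
    into a Risk Indicator Map by a maximum-risk overlay (Liebig's law of the
    minimum), and cross-tabulates the result against concession and
    land-use-plan zones to produce area tables and ranked expansion
    recommendations. Includes a synthetic landscape generator with
    controllable class proportions and spatial autocorrelation so the whole
    pipeline is testable without proprietary provincial GIS data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
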