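Package: coralpore
Title: Micro-CT Porosity Mapping of Coral Skeletons and the Endolithic
    Green Band
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies intra-colonial porosity microenvironments in
    X-ray microtomograms of massive coral skeletons. Provides masking and
    four-phase segmentation of grayscale volumes (solid carbonate,
    sub-resolution micropores, macropore voids, and excluded mask),
    windowed porosity mapping at 0.9 mm intervals (microporosity,
    macroporosity, total porosity and solid volume fraction), vertical
    profile extraction with coordinate and variable normalization, LOESS
    peak and valley localization against the stereoscope-measured green
    band, and the zone, species and location statistics used to compare
    microenvironments. A synthetic phantom generator with exact phase
    ground truth drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    yaml,
    jsonlite,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
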