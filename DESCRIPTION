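Package: viacool
Title: Cell Viability, Marker Positivity and Cooling Kinetics for 3D Neural Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-channel 3D confocal stacks of neural
    cells cultured in collagen hydrogels under therapeutic-hypothermia
    protocols: a synthetic confocal scene generator with exhaustive ground
    truth, image conditioning (bidirectional scan-line correction, 3D median
    filtering, histogram thresholding, de-speckling), automated live/dead
    viability and marker-positivity calling via bounding-box colocalization,
    per-cell immunofluorescence expression quantification with level-set
    outlining and noise-floor gating, a separable eigenseries solution of
    transient heat conduction in a finite cylinder for sample cooling
    kinetics, and rank-based multi-group statistics with compact letter
    displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
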