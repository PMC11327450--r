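Package: spheroidquant
Title: Quantitative Image Analysis of 3D Spheroid Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification chain for spheroid cultures: brightfield
    morphometry (diameter, eccentricity, dissociated-cell area fraction),
    single-cell 3D volumetrics from instance label volumes (nuclear volume
    filtering, spheroid-mask reconstruction by iterated binary closing,
    density, void region, Ki-67 proliferation index), subcellular
    nuclear-to-cytoplasm intensity ratios with automatic background
    correction, convex-hull distance-to-rim spatial profiling, and
    cryosection integrated-density differentiation ratios. Includes seeded
    synthetic-data generators with ground truth so the whole chain is
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    digest,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
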