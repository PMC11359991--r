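Package: aquaperm
Title: Water-Based Dielectric Modelling of Biological Tissues at Microwave
    Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the complex relative permittivity of biological
    tissues in the 1-20 GHz band from their gravimetrically measured water
    content.  Implements a one-pole Cole-Cole dispersion model whose static
    permittivity is obtained from effective-medium mixture theory (Fricke's
    formula for high-water-content tissues, Maxwell's formula for fat),
    together with the dehydration analysis that estimates water content from
    oven-drying weighing campaigns, a synthetic weighing-campaign generator
    for validation, and tooling to compare reconstructed spectra against
    literature reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
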