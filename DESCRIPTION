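Package: polydrop
Title: Poisson Occupancy Statistics for Microbead Encapsulation in
    Polydisperse Emulsions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of microbead encapsulation in polydisperse
    water-in-oil emulsions. Converts in-plane droplet diameters measured under
    slab confinement (slide/coverslip) to droplet volumes, fits zero-truncated
    Poisson occupancy distributions to bead-per-droplet histograms by least
    squares, derives expected encapsulation rates from bead dose and mean
    droplet volume, and corrects for droplet polydispersity with a
    volume-binned mixture of Poisson distributions weighted by aqueous-volume
    share. Includes a synthetic emulsion generator with volume-proportional
    bead loading and an optional bead-aggregation (cluster) model, so every
    analysis stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
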