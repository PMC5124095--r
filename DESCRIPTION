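Package: barCT
Title: Micro-CT Carbonate Budgets from Bioerosion Accretion Replicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies coral-reef carbonate budgets from paired pre- and
    post-deployment micro-CT scans of dead coral skeleton blocks (bioerosion
    accretion replicates). Registers and partitions scan pairs into accretion,
    macroboring, grazing and microboring signals, calibrates X-ray attenuation
    to calcium carbonate density with aragonite phantoms, computes
    calcification and oxygen fluxes from closed-chamber incubations via the
    alkalinity anomaly technique, solves the seawater carbonate system, and
    fits pH-response generalized linear models including the net
    calcification-to-dissolution crossing pH. A synthetic-data module
    generates every input with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, jsonlite, tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
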