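Package: radcell
Title: Cell-Level Dosimetry, Speciation and Radiobiology Assay Analysis for
    Radionuclide Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing in vitro exposures of cell
    cultures to a radionuclide dissolved in the culture medium, built around
    the beta-emitter silver-111. Implements MIRD-schema cellular dosimetry
    (absorbed dose from activity concentration via S-values and the decay
    integral, exposure planning and time-matched activity series, the
    cytoplasm-internalization scenario), an Ag-Cl aqueous speciation solver
    (free ion, AgCl and AgCl2- complexes, AgCl(s) saturation), clonogenic
    assay reduction (plating efficiency, surviving fraction, weighted
    linear-quadratic fits with a non-negative quadratic term, isoeffect
    doses and relative biological effectiveness), and quantification of
    DNA-damage foci and micronuclei in two-channel fluorescence images
    (difference-of-Gaussians spot detection with a median-background-SD
    threshold rule). Synthetic generators for colony-count tables and
    micrograph pairs with ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
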