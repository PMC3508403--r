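Package: benthicN
Title: Isotope-Pairing Inference of Benthic Nitrogen Loss
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers benthic denitrification and anammox rates from
    15N-labelled N2 isotope-ratio time series using the (revised) isotope
    pairing technique. Converts raw 29N2/28N2 and 30N2/28N2 ratio series to
    excess concentrations relative to air, estimates production rates with
    significance and delay filters, partitions N2 production between anammox
    and denitrification (slurry experiments 1 and 2), inverts the nitrate
    labelling fraction to quantify intracellularly stored nitrate, integrates
    volumetric rates to areal fluxes, computes the water-column nitrogen
    deficit N* and basin-scale annual N-loss budgets, and summarises
    denitrifier versus anammox nirS gene copy numbers. A forward simulator of
    slurry and intact-core incubations with known true rates makes every
    stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
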