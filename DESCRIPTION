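Package: mfpbpk
Title: Maternal-Fetal Physiologically Based Pharmacokinetic Modelling of
    Placental Drug Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A compartmental maternal-fetal physiologically based
    pharmacokinetic (PBPK) simulator focused on placental drug transfer.
    Fetal organ compartments are resolved into blood cells, plasma,
    interstitial and intracellular sub-compartments with a fetus-specific
    fraction unbound; the trophoblast barrier carries independent apical
    influx/efflux and basolateral transfer clearances. Ships a library of
    eight reference drugs (acyclovir, cefuroxime, diazepam, dolutegravir,
    emtricitabine, metronidazole, ondansetron, raltegravir), a reduced
    maternal whole-body core, virtual-population simulation, a local
    sensitivity-analysis driver, and model-evaluation metrics (mean
    prediction error, mean squared error, AUC to the last observation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr
Config/testthat/edition: 3
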