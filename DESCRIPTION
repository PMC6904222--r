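Package: forceglide
Title: Force-Gliding Assay Analysis of Multi-Kinesin Cargo Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing force-gliding assays in which surface-anchored
    kinesin motors, tethered through long dsDNA linkers, transport a gliding
    microtubule cargo. Provides extensible worm-like-chain tether mechanics
    (force, extension and stiffness maps with analytic derivatives), a
    ground-truthed synthetic assay generator at two fidelities (a mechanistic
    motor/cargo tug-of-war simulator and an event-level trace generator),
    fluorescence spot tracking (Laplacian-of-Gaussian detection, sub-pixel
    Gaussian localization, linear-assignment linking with gap closing,
    kymograph velocity extraction, on-axis projection), drive/resist state
    classification with transition and kinetics statistics, two-Gaussian
    stuck/fast velocity decomposition, Bell-Evans rupture-force survival
    analysis of optical-trap pulls, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    signal,
    survival,
    rlang,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
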