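Package: celldosim
Title: Cellular Dosimetry and Radiobiology for Alpha- and Beta-Emitting
    Radioligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In vitro cellular dosimetry and radiobiology pipeline for
    comparing alpha- and beta-emitting radioligands (actinium-225 and
    lutetium-177). Implements embedded decay-chain data with closed-form
    Bateman solutions, cellular S values from a desk-scale alpha
    chord-transport and electron continuous-slowing-down engine,
    uptake/clearance kinetics with time-integrated activity, MIRD-scheme
    dose accumulation, clonogenic dose-response fitting with relative
    biological effectiveness (RBE) estimation, DNA-damage foci counting
    from fluorescence image stacks, competitive-displacement IC50
    fitting, and seeded synthetic-data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
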