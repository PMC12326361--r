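Package: kowtools
Title: Data Reduction for Octanol-Water Partition and Distribution Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining octanol-water partition coefficients (K_OW)
    and distribution coefficients (D_OW) of neutral and ionizable solutes from
    biphasic shake-flask measurements. Implements two data-reduction methods
    for ionizable solutes: extrapolation of measured log D values against the
    aqueous-phase pH to pH 7, and conversion of log D to log P via the
    Henderson-Hasselbalch ionization correction followed by extrapolation to
    zero solute concentration. Includes a forward simulator of the coupled
    acid-base speciation and phase-partitioning equilibrium in a biphasic
    octanol/water system (mass balance, electroneutrality, water
    autoprotolysis) used to validate the methods by parameter recovery, an
    OECD concentration-limit quality-control rule, and screening statistics
    over curated literature values of partition coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
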