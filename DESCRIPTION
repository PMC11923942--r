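Package: mdscreen
Title: Multidimensional-Constrained Suspect Screening for GC-APCI-IM-HRMS
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Suspect screening of hydrophobic organic contaminants measured
    by gas chromatography - atmospheric pressure chemical ionization - ion
    mobility - high resolution mass spectrometry. Candidate features are
    gated on exact mass and isotope pattern, scored continuously on
    retention time and collision cross section against source-aware
    calibrated thresholds, fused with an externally supplied MS2 similarity
    score into a weighted multidimensional score, and ranked with
    best-candidate retention per suspect. Includes suspect-library building
    (adduct exact masses, Kovats-to-Fiehn retention-index conversion,
    threshold calibration), readers and writers for delimited feature
    tables, NIST MSP spectra and fragmentation-scorer input files, and a
    ground-truthed synthetic benchmark for workflow evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'isotopes.R'
    'chem.R'
    'AllClasses.R'
    'retention.R'
    'library-io.R'
    'feature-io.R'
    'scoring.R'
    'screen.R'
    'simulate.R'
    'cli.R'
    'mdscreen-package.R'
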