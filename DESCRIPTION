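Package: granuloflux
Title: Metabolic Profiling of Granulocytes from Extracellular Flux Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for kinetic extracellular-flux measurements
    (extracellular acidification rate, ECAR, and oxygen consumption rate,
    OCR) of granulocyte monolayers in 96-well plate assays. Computes the
    standard glycolysis and mitochondrial stress-test parameters from
    injection-segmented rate traces, quantifies agonist-stimulated oxygen
    consumption responses (peak height, kinetic class, glucose-oxidation
    index), estimates rates from raw oxygen-level traces with a sulfite
    zero-oxygen calibration valid under hypoxia, implements the convex-hull
    area-ratio shape statistic for cell contours, and provides the
    normality-gated group comparison scheme used for such data. A
    ground-truth plate simulator with presets for eosinophil and neutrophil
    assays supports validation and power exploration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
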