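Package: gliaquant
Title: Stereology, Astrocyte Calcium Imaging, and Minimal-Stimulation
    Synaptic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design-based stereological estimators for fluorescence
    micrographs (Cavalieri reference volumes, optical-disector numerical
    densities with unbiased counting-frame rules, soma volumes from
    serial-plane areas, background-corrected soma intensities),
    threshold-based detection of calcium transients in dF/F0 traces with
    basal versus post-stimulus windowing, and minimal-stimulation synaptic
    analysis (efficacy, potency, probability of release, recording
    stability checks, and per-synapse potentiation/depression calls).
    Every estimator ships with a seeded synthetic-data generator carrying
    ground truth, so the whole pipeline is validated by parameter
    recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
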