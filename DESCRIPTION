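Package: ringcompass
Title: Heading-Direction Ring Network Analysis for Larval Zebrafish Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of heading-direction ring attractor networks
    recorded with volumetric calcium imaging in head-restrained larval
    zebrafish. Provides fluorescence preprocessing (rolling-baseline dF/F,
    median filtering, z-scoring), swim-bout detection and trimodal
    left/forward/right classification from tail traces, anticorrelation-based
    selection of ring neurons, a rotated principal-component circular
    embedding anchored to anatomy, population-vector decoding of the network
    phase, bump-profile and tuning-curve characterization, heading integration
    from motor commands with phase-heading coupling statistics, exponential
    motor/gaze regressors with cross-validated phase regression, SWC neuron
    skeleton morphometry of the interpeduncular projection, two-dimensional
    spatial autocorrelation of neuropil activity, and a synthetic
    ring-attractor session generator with ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'behavior.R'
    'utils-circular.R'
    'synthio.R'
    'headnav.R'
    'ipnmap.R'
    'phasedyn.R'
    'rpcspace.R'
    'ringdetect.R'
    'traceprep.R'
    'pipeline_io.R'
    'ringcompass-package.R'
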