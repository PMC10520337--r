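Package: sleepAvalanche
Title: Neuronal Avalanche Criticality Analysis for Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and statistical characterization of neuronal avalanches
    in multichannel sleep EEG, and their coupling with sleep macro-architecture
    (hypnogram) and micro-architecture (cyclic alternating pattern, CAP).
    Provides z-score normalization and threshold-based avalanche extraction,
    maximum-likelihood fitting of truncated power laws with Kolmogorov-Smirnov
    goodness and log-likelihood-ratio model comparison, size-duration scaling
    analysis with the crackling-noise scaling relation, branching-parameter
    estimation, sliding-window avalanche density, phi-coefficient coupling of
    avalanche occurrence with sleep stages and CAP phases, and a fully seeded
    synthetic-data suite (critical branching processes, surrogate polysomnograms
    with architecture-coupled burst injection) for end-to-end validation against
    mean-field directed percolation predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'architecture.R'
    'branching.R'
    'coupling.R'
    'density.R'
    'detect.R'
    'groupstats.R'
    'ingest.R'
    'pipeline.R'
    'powerlaw.R'
    'scaling.R'
    'sleep-io.R'
    'sleepAvalanche-package.R'
    'surrogate.R'
    'utils-intervals.R'
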