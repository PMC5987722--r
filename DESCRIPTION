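Package: domainscope
Title: Quantitative Analysis of DNA Replication Domains from Correlative
    Confocal and Super-Resolution Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the internal ultrastructure, spacing and
    mechanical coupling of DNA replication domains (RDs) in mammalian nuclei
    from correlative confocal-STORM imaging data. Implements quality control
    of single-molecule localization event lists (photon filtering,
    correlation-based drift correction, Fourier ring correlation resolution
    gating), confocal-STORM rigid registration with moving z-projections,
    density-based clustering (DBSCAN) of co-replicating stretches with
    per-domain morphometrics (stretch counts, intra-domain nearest-neighbor
    distances, Feret diameters), cross-channel nearest-neighbor spacing of
    dual-color labeled domains, displacement-correlation-angle analysis of
    paired trajectories with a two-regression transition-point estimate, and
    DNA combing length calibration. A synthetic-data generator emulates the
    imaging modalities so every estimator is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
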