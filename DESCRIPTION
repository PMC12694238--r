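Package: rheomicro
Title: Electrical-Impedance Assessment of Scalp Microcirculation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for per-cardiac-cycle analysis of synchronized
    bioimpedance (rheography), electrocardiogram and laser Doppler
    flowmetry (LDF) recordings acquired during intraoperative monitoring
    of scalp microcirculation. Provides a synthetic-recording generator
    with embedded ground truth, Pan-Tompkins R-peak detection and cycle
    segmentation, the full per-cycle metric battery (pulse impedance
    amplitude, rheographic index, differential-rheogram fiducials, LVET,
    pulse-wave transit times, volumetric blood filling via an
    impedance-plethysmography model, LDF cardiac-band amplitude),
    stage-wise statistics with Mann-Whitney tests, Pearson and normalized
    mutual-information association matrices, and density-based clustering
    of functional parameter groups with silhouette-driven hyperparameter
    selection and t-SNE visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    cluster,
    data.table,
    jsonlite,
    yaml,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
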