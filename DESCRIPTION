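Package: DSBrate
Title: Spontaneous DNA Double-Strand-Break Rates from Fluorescent Focus Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative framework for measuring spontaneous DNA
    double-strand-break (DSB) rates from fluorescent end-binding-protein
    (GamGFP-style) focus data in growing bacterial microcolonies. Provides
    detection-efficiency calibration against a gamma-ray dose-response with a
    known break yield, foci-per-division rate inference in branching
    microcolonies with focus-induced division arrest, conversion of legacy
    frequency-based break rates, two-channel focus co-localization geometry
    (overlap fractions, near/far interfocal distances, single/double-marker
    category counting), delta-Ct relative ori:ter copy number, a
    difference-of-Gaussians spot caller for synthetic fluorescence images, and
    a synthetic-data generator covering every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, CellBiology, Microscopy, TimeCourse, StatisticalMethod
RoxygenNote: 7.3.3
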