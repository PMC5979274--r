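Package: atrprofiler
Title: Region-Based Structural Profiling of ATR-FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric profiling of mid-infrared (ATR-FTIR) absorbance
    spectra of plant tissue. Implements region-based, baseline-corrected
    peak-height and trapezoidal peak-area extraction with second-derivative
    (Savitzky-Golay) resolution of overlapped bands; a declarative region
    scheme shipping the alfalfa amide/carbohydrate/lipid defaults; nested
    mixed-model univariate statistics (REML, Satterthwaite degrees of
    freedom, Tukey-Kramer letter groups, studentized-residual outlier
    screening, wild-type versus transgenic contrast); region-wise
    hierarchical clustering (Ward on squared Euclidean distances) and
    principal component analysis of spectra; and a calibrated synthetic
    band-mixture spectrum generator so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    pracma,
    lme4,
    lmerTest,
    emmeans,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
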