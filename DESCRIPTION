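Package: silglyco
Title: Absolute Quantitation and Fc Glycosylation Profiling of
    Antigen-Specific IgG by Stable-Isotope-Labeled Standard LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Targeted processing of centroided MS1 LC-MS data for
    simultaneous absolute quantitation and Fc N-glycosylation profiling of
    antigen-specific IgG1 (and optionally IgG3) tryptic (glyco)peptides,
    using a spiked stable-isotope-labeled IgG1 protein standard. Implements
    elemental-composition and isotopologue-pattern chemistry for natural and
    13C/15N-labeled peptides, retention-time-windowed sum spectra from mzXML,
    calibrant-based mass recalibration, windowed isotopologue-cluster
    integration with coverage correction and pattern-quality metrics,
    negative-control-based spectral curation, consensus analyte selection,
    ratio-based concentration estimation against the spiked standard, and
    relative glycoform profiles with derived glycosylation traits. A
    synthetic-spectrum generator with full ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
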