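Package: cilfahfa
Title: Chemical Isotope Labeling LC-MRM-MS Workflow for FAHFA Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling branched fatty acid esters of hydroxy fatty
    acids (FAHFAs) by chemical isotope labeling (DMED/d4-DMED) liquid
    chromatography multiple-reaction-monitoring mass spectrometry.
    Implements combinatorial MRM transition design from fatty-acyl building
    blocks, scheduling of transition lists into acquisition methods,
    light/heavy peak-pair screening of MRM chromatograms, retention-index
    calibration against a homologous fatty-acid calibrant series, binary
    linear retention-index prediction models for FAHFA regioisomers, and
    retention-index-matching annotation.  A synthetic chromatogram
    generator with known ground truth makes every stage and the end-to-end
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    readxl,
    mzR,
    optparse
Config/testthat/edition: 3
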