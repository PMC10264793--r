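Package: organodose
Title: Drug Transport and Exposure-Corrected Dose-Response Analysis for
    Organoid Culture Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates small-molecule chemotherapeutic transport in three
    patient-derived organoid culture platforms (drug in media, organoids in a
    static hydrogel under a media overlay, and a perfused multi-well
    bioreactor with a recirculating reservoir), derives region-resolved
    exposure metrics (area under the concentration-time curve, day-7 mean
    concentration, fraction of applied dose), and fits exposure-corrected
    four-parameter logistic dose-response curves (IC50/EC50) with
    extra sum-of-squares F-test curve comparison. Includes a synthetic assay
    generator (endpoint luminescence viability, cumulative lactate
    time series, organoid morphometrics) so the full analysis pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
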