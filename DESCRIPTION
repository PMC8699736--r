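Package: svagree
Title: Agreement, Trending and Error-Grid Analysis for Stroke Volume Monitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Method-comparison statistics for validating non-invasive stroke
    volume (SV) monitors against an echocardiographic reference in graded
    central hypovolaemia: Bland-Altman analysis adapted for repeated
    measurements over a range of stroke volumes, percentage error,
    four-quadrant trend concordance with a central exclusion zone, and a
    clinician-opinion error-grid analysis that scores measurement errors by
    their potential for patient harm. Includes a synthetic lower body
    negative pressure (LBNP) cohort simulator with configurable device error
    models and a synthetic expert-questionnaire generator, so every stage of
    the pipeline can be exercised and tested without access to volunteer
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
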