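Package: anemowhisk
Title: Analysis of Whisker-Mediated Wind Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how facial whiskers transduce airflow:
    whisker-tip displacement statistics from pose-tracking tables,
    whisker and follicle morphometrics with a permutation test over
    spatial arrangements on the whisker pad, peri-stimulus
    characterization of cortical wind responses (Poisson-GLM response
    classification, latency, stimulus mutual information), and
    contingency analyses of anemotaxic turning behavior. Includes a
    fully seeded synthetic-data generator that emulates the statistical
    structure of such recordings, exact small-sample rank tests, and a
    pipeline driver producing tidy result tables.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
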