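Package: rollcompact
Title: Roll Compaction Modelling and Ribbon Solid Fraction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Modelling and analysis chain for roll compaction/dry granulation:
    fits material compression descriptors (compressibility index, Heckel yield
    pressure) from in-die tableting records, computes maximum roll pressure and
    pressure-angle/pressure-time profiles from the Johanson rolling theory,
    derives dwell times at a pressure threshold, predicts the at-gap ribbon
    solid fraction through the Midoux number, and reduces ribbon-collection,
    pycnometry and fracture-test records to solid fractions, prediction
    accuracies and tensile strengths. Includes a seeded synthetic-data
    generator emulating the measurement chain and a config-driven study runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
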