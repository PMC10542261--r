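Package: herbmars
Title: Herbal Chemical Marker Ranking, Costing and Audit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting chemical markers for the quality control of
    herbal raw materials with a modified Herbal Chemical Marker Ranking System
    (Herb MaRS).  Structured evidence dossiers for candidate phytochemical
    markers (documented bioactivities, reported concentrations, analytical
    reference-standard listings and assay methods) are scored on a six-component
    additive 0-8 rubric; concentrations reported in percent w/w, mg/g or ppm
    are normalized to parts per million; reference-standard pack prices are
    normalized to cost per smallest denomination; candidates are ranked per
    plant and assigned qualitative or quantitative analytical roles; scored
    tables are audited for internal consistency; and negative markers are
    checked against regulatory concentration limits.  Ships a fully encoded
    evidence dataset for seven medicinal plants widely used in Ugandan herbal
    manufacturing, plus a seeded synthetic-data generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stringi,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
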