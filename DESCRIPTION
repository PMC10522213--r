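Package: bcagree
Title: Method Agreement and Observer Reliability for Skinfold Body-Composition Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for method-comparison studies of body-fat estimation in
    adult women. Implements skinfold-based body-density prediction (the
    Jackson-Pollock-Ward 3-site and Petroski 4-site equations), the Siri
    two-compartment conversion to percent body fat, and the agreement
    statistics used to compare indirect methods against a dual-energy X-ray
    absorptiometry (DXA) reference: Lin's concordance correlation
    coefficient, the St. Laurent gold-standard agreement coefficient,
    Bland-Altman limits of agreement, paired-difference tests, and
    precision-based sample-size planning for the intraclass correlation.
    Includes inter- and intra-observer reliability analysis of triplicate
    skinfold sessions, a seeded synthetic-cohort generator for testing and
    power exploration, and CSV-based pipeline orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
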