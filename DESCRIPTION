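Package: incompfs
Title: Feature Selection and Classification for Incomplete Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores features of incomplete gene-expression matrices against a
    class variable with a modified chi-square independence test that
    redistributes missing-value mass into the observed contingency table
    (no pre-imputation), stabilizes small-sample tables by recursive
    adjacent-row aggregation, and ranks features by p-value. A forward
    best-first search wrapped around a majority-voting extreme learning
    machine ensemble then finds the best top-ranked feature prefix, with
    mean and k-nearest-neighbour imputation applied only to the selected
    subset. Includes stratified cross-validation, one-vs-rest metrics and
    a seeded synthetic-data generator with known informative features.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
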