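Package: soilhomog
Title: Diagnosing Mechanisms of Soil Bacterial Community Homogenization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing biotic homogenization of soil bacterial
    communities after land-use change, from paired RNA- and DNA-inferred
    OTU tables. Provides rarefaction-averaged community tables, Canberra
    community and Gower environmental (dis)similarity, distance-decay
    regression with Mantel and partial Mantel permutation inference,
    randomization-based comparison of decay slopes, PERMANOVA, a
    negative-binomial Wald test for differential abundance, and the
    "newcomer"/"bloomer" removal analyses that attribute homogenization
    to environmental convergence, biotic invasion, or range expansion.
    Includes a spatially explicit generator of paired RNA/DNA communities
    for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    cluster,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
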