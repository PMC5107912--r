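Package: diatomASF
Title: Sampling-Frequency Design for Daily Stream Community Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides how often a stream community must be sampled to track
    its temporal dynamics. Daily taxon-abundance profiles are classified into
    temporal clusters with a batch-trained Kohonen self-organizing map (SOM)
    followed by Ward clustering of the codebook, validated by the
    multi-response permutation procedure (MRPP). Within each cluster the
    percentage similarity index (PSI) is averaged over increasing sampling
    intervals and the appropriate sampling frequency (ASF) is read off a
    similarity threshold, with explicit censoring. An antecedent precipitation
    index (API) with seasonally varying decay links the ASF to catchment
    wetness. A synthetic community generator with analytically known PSI decay
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
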