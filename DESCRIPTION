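Package: sigscreen
Title: Transcriptional-Signature Compound Screening from Targeted Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for targeted-transcriptomic (RASL-seq style)
    compound screens run on multiwell plates. From raw wells-by-probes count
    matrices it applies cell-count and read-depth quality filters, normalizes
    each well to the sum of housekeeping probes, derives a knockout-versus-
    wild-type signature gene set (fold-change and Welch t-test thresholds,
    with Ward-clustering control-well outlier removal), standardizes the
    signature genes, and scores every compound-treated well by its Euclidean
    distance to the wild-type centroid, calling transcriptional-mimetic hits
    relative to the knockout-to-wild-type reference distance. A negative-
    binomial synthetic-screen generator with ground truth supports end-to-end
    recovery testing, and a helper normalizes orthogonal per-well phenotype
    measurements across batches to the knockout mean.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
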