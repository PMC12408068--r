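Package: loophub
Title: Loop Topology of Methylation-Sensitive CTCF Peaks Near Nuclear Speckles
Version: 0.1.0
Authors@R: person("Ada", "Reyes", email = "ada.reyes@example.org", role = c("aut", "cre"))
Description: A tested pipeline for chromatin loop-anchor topology built around
    methylation-sensitive CTCF peaks. Derives condition-specific peak sets from
    replicate ChIP-seq calls, counts distinct HiChIP loops per peak and calls
    "highly looping" peaks with a superenhancer-style tangent cutoff on the rank
    curve, applies PET/FDR loop filters and a transparent CPM fold-change,
    stratifies loops by nuclear-speckle (SON Cut&Tag-like) signal deciles and a
    90th-percentile speckle-association rule, computes observed/expected contact
    pileups with strand reflection and blacklist exclusion, and clusters
    differential genes (K-means, K = 4) with cluster-level CTCF and speckle
    covariates. A truth-labelled synthetic-data generator plants every effect the
    pipeline is designed to detect, so all stages are testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    optparse,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
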