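Package: behaveseq
Title: Behavior-Anchored Reconstruction of Minute-Resolution Developmental Transcriptomes
Version: 0.1.0
Authors@R:
    person("BehaveSeq", "Developers", email = "behaveseq@example.org", role = c("aut", "cre"))
Description: Infers the developmental age of individually tracked C. elegans
    larvae from their locomotion traces (hatch detection and lethargus-midpoint
    stage transitions), joins those ages to single-animal RNA-seq count
    matrices, and reconstructs minute-resolution developmental gene-expression
    trajectories from asynchronously collected individuals. Includes
    correlation-versus-time-gap diagnostics, t-SNE sample embedding,
    artificial hourly pooling against reference time courses, hierarchical
    clustering of temporal profiles with a correlation distance, per-time-bin
    nonparametric differential expression between genotypes, and a small
    multilayer-perceptron regressor that predicts developmental age from an
    expression profile. A synthetic-data generator with planted ground truth
    (staged locomotion tracks and parametric expression archetypes) backs the
    test suite end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
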