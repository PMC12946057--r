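Package: taha
Title: Transferable Attention Head Alignment and Pruning for Vision
    Transformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cross-species transfer of Vision Transformer attention heads
    for plant phenotype image classification. Provides a small trainable
    ViT backbone that exposes per-head attention maps, a Kullback-Leibler
    domain alignment loss between a frozen source model and an adapting
    target model, a phenotypic consistency constraint, per-head
    transferability scores with dynamic-threshold pruning, physical model
    surgery that rebuilds the reduced output projection, exact parameter
    and multiply-accumulate accounting, a procedural two-domain plant
    image generator with planted head-relevant structure, and an
    iterative align-score-prune-finetune pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
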