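Package: varqform
Title: Hierarchical Query-Transformer Fusion for Genomic Variant Captioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hierarchical multimodal architecture for genomic
    variant interpretation: modality-specific querying transformers (Q-formers)
    that align precomputed biological embeddings (DNA sequence bins, gene
    neighborhoods, protein pairs) with structured JSON variant captions through
    contrastive, matching and grounded-generation losses; a master fusion
    Q-former that emits a fixed-length multimodal prefix for a frozen causal
    text decoder; the caption construction pipeline (variant-ID parsing,
    nearest-gene neighborhoods, track filtering); evaluation harnesses for
    per-field annotation accuracy, target-gene identification with
    closest-gene stratification, and grouped variant prioritization; and a
    synthetic multi-omics generator so the whole system is exercisable at desk
    scale. Training runs on a compact reverse-mode automatic-differentiation
    engine included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
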