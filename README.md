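# varqform

Hierarchical query-transformer fusion for genomic variant captioning, in R.

## The problem

Interpreting a single-nucleotide variant (SNV) means integrating evidence at
several biological scales: the regulatory DNA context around the variant, the
identity and distance of nearby protein-coding genes, and the protein-level
change it may induce. Modern biological foundation models emit rich
embeddings for each of these modalities, but the embeddings are
variable-length, high-dimensional and mutually incompatible — and the
reasoning engines we would like to hand them to (causal text decoders) expect
token sequences.

`varqform` implements a hierarchical querying-transformer (Q-former)
architecture that bridges this gap:

1. **Modality Q-formers (Stage 1).** For each modality m, a small transformer
   holds K learnable query vectors that cross-attend to the modality's
   embedding rows and distill them into exactly K output tokens
   (K = 32 for the interleaved ref/alt DNA sequence bins, 8 for the
   gene-neighborhood table, 8 for the ref/alt protein pair). Each Q-former is
   aligned to structured JSON variant captions with three simultaneous
   losses:
   * **ITC** — symmetric in-batch InfoNCE on l2-normalised query/caption
     projections `q̂`, `t̂` with learnable temperature τ:
     `L_ITC = −½ E[ log exp(q̂ᵀt̂/τ)/Σⱼ exp(q̂ᵀt̂ⱼ/τ) + log exp(t̂ᵀq̂/τ)/Σⱼ exp(t̂ᵀq̂ⱼ/τ) ]`
   * **ITM** — binary matching head over mean-pooled query outputs, with hard
     negatives sampled from the ITC similarity matrix;
   * **ITG** — causal caption generation with the query tokens visible to
     every text position.
   The Stage-1 objective is the plain sum `L = Σᵢ L_ITC(i) + L_ITM(i) + L_ITG(i)`
   over the N modality Q-formers.
2. **Master Q-former (Stage 2).** 32 meta-query vectors are concatenated with
   a tokenized instruction, self-attend jointly, and cross-attend to the
   layer-normalised concatenation of all Stage-1 tokens every second layer.
   The 32 refined meta-queries are projected (`W_proj`) into the embedding
   space of a **frozen** causal text decoder and prepended as a multimodal
   prefix. Training is next-token prediction on answer tokens only (prompt
   positions masked with the ignore index); the decoder receives no gradient,
   ever.

Everything runs at desk scale on one CPU: the package ships a synthetic
multi-omics generator (latent-linked embeddings + captions), a tiny frozen
decoder stand-in, a reverse-mode autodiff engine the transformers train on,
the caption-construction pipeline (variant-ID parsing, nearest-gene
neighborhoods, genome-build filters, top-k track selection), and evaluation
harnesses for per-field annotation accuracy, target-gene identification with
closest-gene stratification, and grouped variant prioritization.

## Worked example

```r
library(varqform)

# 128 synthetic variants: three modality embeddings + a JSON caption each
items <- gen_variant_dataset(128, seed = 7)
cat(items[[1]]$caption$json)
#> {"chromosome":"1","variant_type":"noncoding","consequence":"intron_variant",
#>  "nearest_genes":["G1_02","G1_03","G1_01","G1_04","G1_05","G1_06","G1_07","G1_08"],
#>  "cell_types":["cardiomyocyte","keratinocyte","neuron"]}

# Stage 1 at desk scale: width 32, 2 layers, one modality, ~35 s
cfg <- train_config(lr = 1e-3, epochs = 4, batch_size = 16, seed = 1)
fit <- train_stage1(items, cfg, modalities = "sequence")
tail(fit$history[, c("step", "sequence_itc", "sequence_itm",
                     "sequence_itg", "sequence_retrieval")], 1)
#>    step sequence_itc sequence_itm sequence_itg sequence_retrieval
#> 32   32        1.593    0.6552587     3.526751              0.375

eval_retrieval(fit$models$sequence, items, fit$vocab, "sequence")
#> [1] 0.3984375       # chance is 1/16 = 0.0625
```

The contrastive loss falls from ~3.0 to ~1.6 and in-batch retrieval reaches
40% against a 6.25% chance level: the query tokens have learned to identify
their own caption among the batch. The prioritization scorer reproduces the
analytic random baseline exactly:

```r
res <- random_ranking_reference(10)
unlist(res)
#>  top_k.top1 top_k.top2 top_k.top3 mean_rank  sd_rank
#>        0.10       0.20       0.30      5.50 2.872281
```

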