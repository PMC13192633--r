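---
title: "Hierarchical query-transformer fusion for variant captioning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical query-transformer fusion for variant captioning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(varqform)
```

This vignette is the package's own account of its model, its assumptions,
and the design decisions taken where the design was genuinely open. It
states no empirical number that the test suite or `scripts/acceptance.R`
does not itself compute.

## The model

A *querying transformer* (Q-former) distills a variable-length matrix of
input embeddings into a fixed number K of learned query vectors. The K
queries self-attend, and on every `cross_attn_period`-th layer (0-based
even layers by default) cross-attend to the input rows, so the output is
always exactly K tokens of width `hidden_dim` whatever the input length.
The package's full-scale configuration is 12 layers, width 128, 8 heads,
feed-forward width 4x, with 32 queries for the DNA-sequence modality and 8
each for the gene-neighborhood and protein modalities; the desk-scale
profile used throughout the tests is width 32, 2 layers, 4 heads, with the
same query counts.

Three modalities feed the system, each a precomputed embedding that is
**never** updated (inputs enter the computation graph as constants):

* **sequence** — B reference bins and B alternate bins interleaved into a
  2B-row matrix (`interleave_ref_alt()`), ref at even 0-based offsets;
* **gene** — up to 15 nearest protein-coding genes, one embedding row per
  gene, each row carrying two appended feature columns: `log1p` of the bp
  distance to the gene interval and a 0/1 overlap flag;
* **protein** — two rows, the reference and alternate protein embedding of
  the closest gene.

### Stage 1: caption alignment

Each modality Q-former is aligned to structured JSON variant captions
(fields in fixed order: chromosome, variant_type, consequence,
nearest_genes, cell_types) with three simultaneous objectives:

* **ITC** (contrastive): symmetric in-batch InfoNCE over l2-normalised
  projections with a learnable temperature stored as a log-temperature and
  initialised so that 1/tau = 14.3. The per-pair similarity is the
  *maximum* over the K query projections of the cosine against the pooled
  caption projection: the architecture emits K queries but the contrastive
  objective is written for a single query vector, and max-pooling is the
  standard resolution in the vision-language fusion family this design
  follows. The aggregation is isolated in one place and easy to swap.
* **ITM** (matching): a two-way head on mean-pooled query outputs, run
  with fully bidirectional query/caption attention. Each item contributes
  one positive and two hard negatives (one caption, one embedding) sampled
  proportionally to the softmax of the off-diagonal ITC similarities.
* **ITG** (grounded generation): causal language modeling of the caption
  with all query tokens visible to every text position.

One parameter set serves the query and text sides: queries and caption
tokens run through the same self-attention stack under task-dependent
masks (separate streams for ITC, bidirectional for ITM, causal text for
ITG). The text-encoder depth and width are therefore those of the
Q-former itself — the alignment design leaves them open, and sharing keeps
one parameter set. The Stage-1 loss is the plain unweighted sum of all
nine terms (3 losses x 3 modalities); the formulation gives no weights, so
none are introduced.

### Stage 2: master fusion and the frozen decoder

The master Q-former (full scale: 6 layers; desk scale: 2) holds
N_m = 32 meta-queries. They are concatenated with the tokenized
instruction; the joint sequence self-attends, and the meta-query positions
cross-attend — on every second layer — to the layer-normalised
concatenation of all Stage-1 tokens (fixed order: sequence, gene,
protein). Only the meta-query positions are emitted, projected by
`W_proj` into the decoder's embedding space: a 32-vector multimodal
prefix, whatever the modality subset or instruction length.

The decoder is frozen: its weights enter every forward as constants, so
the next-token loss (answer positions only; prefix and prompt masked with
the ignore index) reaches the projection, the master, and the Stage-1
Q-formers — and nothing else. During Stage 2 the Stage-1 models receive
*only* the NTP gradient: the training description names exactly the
projection, master and Stage-1 weights as what the loss updates, which
reads as NTP-only, and that is what is implemented. Instruction
embeddings come from the master's own embedding table, not the decoder's
(the choice is open; a dedicated table keeps the master self-contained
and is configurable by swapping the embedding step).

## Optimization

AdamW (weight decay 0.05) under a cosine schedule with linear warmup over
10% of steps (learning rate 0 at step 0, peak at the end of warmup),
global gradient clipping at norm 1.0. The full-scale default peak rate is
1e-4 over 15 epochs. The desk-scale profile trains with a peak rate of
1e-3: at width 32 with a few hundred examples the 1e-4 rate moves the
tiny models too slowly for any loss to approach its asymptote within
minutes, and 1e-3 is the conventional rate for transformers this small.
Mixed precision is off: every run is bitwise reproducible given its seed.
Everything trains on the package's reverse-mode autodiff engine (dense
matrices, fused layer ops with hand-written backward passes, each checked
against central finite differences in the test suite).

## The synthetic generator

`gen_variant_dataset()` emulates the three modalities as noisy linear
images of a one-hot latent variant code (fixed random maps per seed,
Gaussian noise sd 0.1): the simplest construction that guarantees the
caption is recoverable from the embeddings, so alignment is learnable by
construction. The information layout mirrors where each signal would live
in real data: the sequence modality carries chromosome, coding status and
consequence; the gene modality carries gene identity and cell types; the
protein modality carries coding status and consequence. Gene identity is
therefore recoverable *only* from the gene modality — the property the
master-ablation experiment needs.

Coordinates are half-open 0-based internally (BED convention) and 1-based
in variant identifiers (`chrom_pos_ref_alt`); conversions are centralized
in `nearest_genes()`. Distance to a gene is the minimal bp gap to its
interval (0 inside), log-distance is `log1p(distance)` — the feature name
fixes neither base nor offset, and `log1p` handles the overlap case
without a special branch. Strand is ignored for distance. Caption JSON
field order is fixed for byte-stable fixtures; the caption lists the full
(<= 15 gene) neighborhood, configurable where a shorter list is wanted.

What the generator does **not** emulate: real sequence content,
linkage structure, QTL colocalisation statistics, realistic consequence
frequencies, or annotation noise. Passing tests therefore demonstrate
that the architecture extracts and routes the information its inputs
contain — not that real foundation-model embeddings contain it.

## Evaluation choices

* Nearest-genes accuracy counts a hit when the predicted and gold gene
  sets intersect (a single reported accuracy fixes no match rule); a
  strict set-equality mode is available.
* Cell types are scored as mean ROUGE-L F1, applied uniformly.
* Rank spread in prioritization uses the *population* standard deviation:
  for uniform ranks over groups of 10 this gives sqrt(99/12) = 2.872,
  matching the analytic reference row to its printed precision.
* Ranked lists are extracted from generated text by first occurrence of
  candidate ids, unmentioned candidates appended in input order.
* Target-gene identification uses exact normalized gene-id match (no
  alias resolution; synthetic ids have no aliases).

## Desk-scale experiment sizes

The test suite runs every experiment at sizes chosen so the full suite
finishes in minutes on one CPU, while each experiment still has the power
to show its effect:

* *Alignment recovery*: 512 variants, batch 16, 2 epochs, sequence
  modality. Chance retrieval is 1/16; the trained model must reach at
  least five times that.
* *Permutation ablation*: the same run against a derangement-permuted
  pairing; retrieval must stay within three binomial standard errors of
  chance and the permuted contrastive trajectory must end above the
  aligned one.
* *Master ablation*: 5 replicates; per replicate, 60 variants against a
  dense 8-gene genome (2 chromosomes x 4 genes, so each gene id recurs
  often enough to be learnable from ~48 training variants), 4 sequence
  bins, QA supervision on the gene and coding-status fields, 2 epochs of
  Stage-1 alignment pretraining shared by both variants (cloned weights),
  then 12 epochs of Stage 2 for each variant — enough for both variants
  to approach their ceiling, which is the regime the comparison is about
  (end-of-training models). With undertrained variants the comparison
  measures optimization speed, not architecture: the no-master linear
  projection converges faster. See the limitations below for what this
  experiment does and does not show at desk scale.
* *Stage-2 contracts*: a small QA run (one field) suffices to check
  frozen-decoder conservation bitwise and learning above the
  majority-class baseline.

## Known limitations

* The frozen decoder stand-in has random (seed-determined) weights; it is
  a reservoir the prefix learns to steer, not a pretrained reasoner. Any
  effect that depends on a pretrained decoder's language competence
  (e.g. zero-shot transfer of reasoning) is out of reach at desk scale.
* In particular, the master-ablation direction (master fusion at least as
  good as direct token prepending on a modality-exclusive field) does not
  reproduce robustly against the random decoder: fully converged
  replicates tie, but replicates just short of their ceiling favor the
  shallower no-master path, because with a random decoder the comparison
  reduces to optimization speed. The advantage attributed to the master —
  instruction-conditioned routing that spares a pretrained decoder from
  attending over a long unrouted prefix — has no purchase when the
  decoder's attention is random. The ablation machinery is exercised and
  reported regardless; its desk-scale outcome should not be read as
  evidence about the full-scale architecture in either direction.
* The autodiff engine is dense and single-threaded; paper-scale
  configurations (12 layers, width 128, 278k variants) are expressible
  but not practical in it.
* ITC max-pooling, the 1-positive/2-negative ITM composition, and the
  shared text trunk are documented conventions where the formulation is
  silent; all three are localized and swappable.
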