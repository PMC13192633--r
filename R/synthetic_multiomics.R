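# Synthetic multi-omics generator.
#
# Emulates the three precomputed embedding modalities (DNA sequence bins,
# gene neighborhood, protein ref/alt pair) as noisy linear images of a
# one-hot latent variant code, paired with deterministic structured captions,
# plus target-gene traces and grouped prioritization benchmarks. Everything
# is a pure function of its seed, so fixtures are rebuilt at run time and the
# alignment signal is learnable by construction.

.vq_consequences <- list(
  coding = c("missense_variant", "synonymous_variant", "stop_gained"),
  noncoding = c("intron_variant", "intergenic_variant",
                "upstream_gene_variant", "regulatory_region_variant")
)
.vq_cell_types <- c("hepatocyte", "neuron", "cardiomyocyte",
                    "T_cell", "keratinocyte", "adipocyte")
.vq_diseases <- c("type_2_diabetes", "asthma", "hypertension",
                  "beta_thalassemia", "crohn_disease")

#' Synthetic genome annotation
#'
#' A few chromosomes with non-overlapping gene intervals in half-open 0-based
#' coordinates, used as the fixture for nearest-gene logic.
#'
#' @param n_chrom number of chromosomes (labels "1", "2", ..., "X" last).
#' @param genes_per_chrom genes per chromosome.
#' @param chrom_length chromosome length in bp.
#' @param seed RNG seed.
#' @return `synthetic_genome` object: list with `chroms` (named lengths) and
#'   `genes` (data frame chrom/start/end/strand/gene_id).
#' @export
synthetic_genome <- function(n_chrom = 4L, genes_per_chrom = 8L,
                             chrom_length = 1e6, seed = 0L) {
  stopifnot(n_chrom >= 1L, genes_per_chrom >= 1L, chrom_length > 0)
  set.seed(seed)
  labels <- c(as.character(1:22), "X")[seq_len(n_chrom)]
  if (n_chrom >= 2L) labels[n_chrom] <- "X"
  genes <- do.call(rbind, lapply(seq_along(labels), function(ci) {
    slot <- chrom_length / genes_per_chrom
    width <- round(stats::runif(genes_per_chrom, 0.05, 0.25) * slot)
    start <- round((seq_len(genes_per_chrom) - 1L) * slot +
                     stats::runif(genes_per_chrom, 0.05, 0.5) * slot)
    end <- pmin(start + width, chrom_length)
    data.frame(chrom = labels[ci], start = as.integer(start),
               end = as.integer(end),
               strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE),
               gene_id = sprintf("G%s_%02d", labels[ci], seq_len(genes_per_chrom)))
  }))
  stopifnot(!anyDuplicated(genes$gene_id), all(genes$end <= chrom_length))
  chroms <- stats::setNames(rep(as.integer(chrom_length), n_chrom), labels)
  structure(list(chroms = chroms, genes = genes), class = "synthetic_genome")
}

# draw one latent variant code against a genome
.draw_latent <- function(genome, p_coding = 0.35) {
  chrom <- sample(names(genome$chroms), 1L)
  pos <- sample.int(genome$chroms[[chrom]], 1L)
  vtype <- if (stats::runif(1) < p_coding) "coding" else "noncoding"
  consequence <- sample(.vq_consequences[[vtype]], 1L)
  alleles <- sample(c("A", "C", "G", "T"), 2L)
  cts <- sort(sample(.vq_cell_types, sample(1:3, 1L)), method = "radix")
  nb <- nearest_genes(chrom, pos, genome)
  list(chromosome = chrom, position = pos, ref = alleles[1], alt = alleles[2],
       variant_type = vtype, consequence = consequence,
       neighborhood = nb, cell_types = cts)
}

.onehot <- function(value, levels) {
  v <- numeric(length(levels))
  v[match(value, levels)] <- 1
  v
}

.multihot <- function(values, levels) {
  v <- numeric(length(levels))
  v[match(values, levels)] <- 1
  v
}

#' Generate a paired multimodal variant dataset
#'
#' Draws `n` latent variant codes against a seeded [synthetic_genome()] and
#' renders, for each: a sequence-modality embedding of `2 * seq_bins`
#' interleaved ref/alt rows, a gene-neighborhood embedding of up to 15 rows
#' (each carrying appended log-distance and overlap columns), a two-row
#' protein embedding (ref, alt), and the structured caption. Each modality is
#' a fixed random linear map of a one-hot encoding of (a subset of) the
#' latent code plus independent Gaussian noise, so the caption is recoverable
#' from the embeddings: the sequence modality carries chromosome, variant
#' type and consequence; the gene modality carries gene identity and cell
#' types; the protein modality carries variant type and consequence.
#'
#' @param n number of variants (>= 1).
#' @param seed RNG seed; equal seeds give bitwise-identical output.
#' @param dims list with `seq_bins` (B, default 8), `seq_dim`, `gene_dim`,
#'   `prot_dim` (all default 16).
#' @param sigma noise standard deviation (default 0.1).
#' @param genome optional [synthetic_genome()]; derived from `seed` if NULL.
#' @return list of `n` items, each `list(record, embeddings, caption)`, with
#'   `embeddings` a named list (sequence, gene, protein) of matrices tagged
#'   with a `modality` attribute. The genome and dims ride along as
#'   attributes.
#' @export
gen_variant_dataset <- function(n, seed = 0L, dims = list(), sigma = 0.1,
                                genome = NULL) {
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1")
  d <- utils::modifyList(list(seq_bins = 8L, seq_dim = 16L,
                              gene_dim = 16L, prot_dim = 16L), dims)
  if (any(unlist(d) <= 0L)) stop("all dims must be positive")
  if (is.null(genome)) genome <- synthetic_genome(seed = seed)
  set.seed(seed)
  chrom_lv <- names(genome$chroms)
  cons_lv <- unlist(.vq_consequences, use.names = FALSE)
  type_lv <- c("coding", "noncoding")
  gene_lv <- genome$genes$gene_id

  # fixed random maps, drawn once per call from the seeded stream
  z_seq_len <- length(chrom_lv) + 2L + length(cons_lv)
  L_seq <- matrix(stats::rnorm(d$seq_dim * z_seq_len), d$seq_dim)
  L_alt <- matrix(stats::rnorm(d$seq_dim * length(cons_lv)), d$seq_dim) * 0.5
  pos_emb <- matrix(stats::rnorm(2L * d$seq_bins * d$seq_dim), 2L * d$seq_bins) * 0.3
  E_gene <- matrix(stats::rnorm(length(gene_lv) * d$gene_dim), length(gene_lv))
  L_cell <- matrix(stats::rnorm(d$gene_dim * length(.vq_cell_types)), d$gene_dim) * 0.7
  E_prot <- matrix(stats::rnorm(length(gene_lv) * d$prot_dim), length(gene_lv))
  L_pcons <- matrix(stats::rnorm(d$prot_dim * length(cons_lv)), d$prot_dim)
  L_ptype <- matrix(stats::rnorm(d$prot_dim * 2L), d$prot_dim) * 0.8

  items <- lapply(seq_len(n), function(i) {
    lat <- .draw_latent(genome)
    z_seq <- c(.onehot(lat$chromosome, chrom_lv),
               .onehot(lat$variant_type, type_lv),
               .onehot(lat$consequence, cons_lv))
    sig <- as.numeric(L_seq %*% z_seq)
    B <- d$seq_bins
    ref_bins <- matrix(rep(sig, each = B), B) + pos_emb[seq_len(B), ] +
      matrix(stats::rnorm(B * d$seq_dim, sd = sigma), B)
    alt_sig <- sig + as.numeric(L_alt %*% .onehot(lat$consequence, cons_lv))
    alt_bins <- matrix(rep(alt_sig, each = B), B) + pos_emb[B + seq_len(B), ] +
      matrix(stats::rnorm(B * d$seq_dim, sd = sigma), B)
    seq_emb <- interleave_ref_alt(ref_bins, alt_bins)

    nb <- lat$neighborhood
    ct_sig <- as.numeric(L_cell %*% .multihot(lat$cell_types, .vq_cell_types))
    gene_rows <- E_gene[match(nb$gene_id, gene_lv), , drop = FALSE] +
      matrix(rep(ct_sig, each = nrow(nb)), nrow(nb)) +
      matrix(stats::rnorm(nrow(nb) * d$gene_dim, sd = sigma), nrow(nb))
    gene_emb <- cbind(gene_rows, log_distance = nb$log_distance,
                      overlaps = as.numeric(nb$overlaps))

    closest <- match(nb$gene_id[1], gene_lv)
    p_sig <- E_prot[closest, ] +
      as.numeric(L_ptype %*% .onehot(lat$variant_type, type_lv))
    prot_ref <- p_sig + stats::rnorm(d$prot_dim, sd = sigma)
    prot_alt <- p_sig + as.numeric(L_pcons %*% .onehot(lat$consequence, cons_lv)) +
      stats::rnorm(d$prot_dim, sd = sigma)
    prot_emb <- rbind(prot_ref, prot_alt)
    rownames(prot_emb) <- NULL

    record <- list(
      variant_id = format_variant_id(lat$chromosome, lat$position,
                                     lat$ref, lat$alt),
      chromosome = lat$chromosome, position = lat$position,
      ref = lat$ref, alt = lat$alt,
      variant_type = lat$variant_type, consequence = lat$consequence,
      nearest_genes = nb$gene_id, cell_types = lat$cell_types,
      neighborhood = nb
    )
    list(record = record,
         embeddings = list(
           sequence = structure(seq_emb, modality = "sequence"),
           gene = structure(gene_emb, modality = "gene"),
           protein = structure(prot_emb, modality = "protein")),
         caption = build_caption(record))
  })
  attr(items, "genome") <- genome
  attr(items, "dims") <- d
  attr(items, "input_dims") <- c(sequence = d$seq_dim,
                                 gene = d$gene_dim + 2L,
                                 protein = d$prot_dim)
  items
}

#' Generate target-gene reasoning traces
#'
#' Each trace pairs a variant with a disease, its gene neighborhood, and an
#' annotated target gene; exactly `round(n * frac_non_closest)` traces have a
#' target that is not the closest gene.
#'
#' @param n number of traces.
#' @param frac_non_closest fraction in [0, 1] of traces whose target gene
#'   differs from the closest gene.
#' @param seed RNG seed.
#' @param genome optional [synthetic_genome()].
#' @return list of traces: `variant_id`, `disease`, `neighborhood` (data
#'   frame as in [nearest_genes()]), `target_gene`, `non_closest` flag.
#' @export
gen_target_gene_traces <- function(n, frac_non_closest = 0.44, seed = 0L,
                                   genome = NULL) {
  stopifnot(n >= 1L)
  if (frac_non_closest < 0 || frac_non_closest > 1) {
    stop("frac_non_closest must lie in [0, 1]")
  }
  if (is.null(genome)) genome <- synthetic_genome(seed = seed)
  set.seed(seed)
  m <- round(n * frac_non_closest)
  flip <- logical(n)
  if (m > 0L) flip[sample.int(n, m)] <- TRUE
  lapply(seq_len(n), function(i) {
    repeat {
      lat <- .draw_latent(genome)
      if (nrow(lat$neighborhood) >= 2L) break
    }
    nb <- lat$neighborhood
    target <- if (flip[i]) sample(nb$gene_id[-1], 1L) else nb$gene_id[1]
    list(variant_id = format_variant_id(lat$chromosome, lat$position,
                                        lat$ref, lat$alt),
         disease = sample(.vq_diseases, 1L),
         neighborhood = nb,
         target_gene = target,
         non_closest = flip[i])
  })
}

#' Generate grouped variant-prioritization benchmarks
#'
#' Builds `n_groups` groups of `group_size` candidate variants sharing a
#' locus, with exactly one candidate per group labeled causal.
#'
#' @param n_groups number of groups.
#' @param group_size candidates per group (>= 2).
#' @param seed RNG seed.
#' @param genome optional [synthetic_genome()].
#' @return list of groups: `group_id`, `candidates` (data frame variant_id /
#'   chromosome / position / ref / alt), `causal_id`.
#' @export
gen_prioritization_groups <- function(n_groups, group_size = 10L, seed = 0L,
                                      genome = NULL) {
  stopifnot(n_groups >= 1L)
  if (group_size < 2L) stop("group_size must be >= 2")
  if (is.null(genome)) genome <- synthetic_genome(seed = seed)
  set.seed(seed)
  lapply(seq_len(n_groups), function(g) {
    chrom <- sample(names(genome$chroms), 1L)
    center <- sample.int(genome$chroms[[chrom]] - 20000L, 1L) + 10000L
    offs <- sort(sample.int(10000L, group_size)) - 5000L
    pos <- center + offs
    alle <- t(replicate(group_size, sample(c("A", "C", "G", "T"), 2L)))
    cand <- data.frame(
      variant_id = format_variant_id(chrom, pos, alle[, 1], alle[, 2]),
      chromosome = chrom, position = pos, ref = alle[, 1], alt = alle[, 2],
      stringsAsFactors = FALSE)
    causal <- sample.int(group_size, 1L)
    list(group_id = sprintf("grp%04d", g), candidates = cand,
         causal_id = cand$variant_id[causal])
  })
}

#' Caption vocabulary of a generated dataset
#'
#' Vocabulary over all caption texts plus the field-name prompts used for
#' decoder supervision.
#'
#' @param items output of [gen_variant_dataset()].
#' @export
dataset_vocab <- function(items) {
  texts <- vapply(items, function(it) caption_text(it$caption), character(1))
  prompts <- paste("predict", c("chromosome", "variant_type", "consequence",
                                "nearest_genes", "cell_types"))
  vq_vocab(c(texts, prompts))
}

#' Per-field question/answer triples for prefix-conditioned decoding
#'
#' Turns generated items into (embeddings, instruction/prompt, answer)
#' triples, one per caption field, with short answers: the field value
#' (closest gene for nearest_genes, the full list for cell_types).
#'
#' @param items output of [gen_variant_dataset()].
#' @param vocab a [vq_vocab()]; built from `items` when NULL.
#' @param fields caption fields to include.
#' @return list with `triples` (list of item/field/embeddings/prompt_ids/
#'   answer_ids/answer_text) and `vocab`.
#' @export
make_field_qa <- function(items, vocab = NULL,
                          fields = c("chromosome", "variant_type",
                                     "consequence", "nearest_genes",
                                     "cell_types")) {
  if (is.null(vocab)) vocab <- dataset_vocab(items)
  triples <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    f <- it$caption$fields
    for (fd in fields) {
      ans <- switch(fd,
        chromosome = f$chromosome,
        variant_type = f$variant_type,
        consequence = f$consequence,
        nearest_genes = f$nearest_genes[1],
        cell_types = paste(f$cell_types, collapse = " "))
      triples[[length(triples) + 1L]] <- list(
        item = i, field = fd,
        embeddings = it$embeddings,
        prompt_ids = vq_encode(vocab, paste("predict", fd)),
        answer_ids = vq_encode(vocab, ans),
        answer_text = ans)
    }
  }
  list(triples = triples, vocab = vocab)
}
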