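# Modality-specific querying transformer (Q-former) and the three Stage-1
# alignment losses: contrastive (ITC), matching (ITM) and grounded caption
# generation (ITG).
#
# One parameter set serves both the query side and the text side: queries and
# caption tokens run through the same self-attention stack under
# task-dependent masks (separate streams for ITC, fully bidirectional for
# ITM, causal text attending to queries for ITG). Cross-attention to the
# modality embedding is applied at query positions only, on every
# `cross_attn_period`-th layer (0-based even layers by default).

#' Q-former configuration
#'
#' Paper-scale defaults: 12 layers, width 128, 8 heads, feed-forward width
#' 4x, cross-attention every 2 layers; 32 queries for the sequence modality,
#' 8 for gene and protein.
#'
#' @param modality one of "sequence", "gene", "protein" (sets the default
#'   query count) or any label when `num_queries` is given.
#' @param input_dim width of the incoming modality embedding rows.
#' @param vocab_size caption vocabulary size.
#' @param num_layers,hidden_dim,num_heads,ff_width,num_queries,cross_attn_period
#'   architecture knobs, see Details.
#' @param contrast_dim shared contrastive projection width.
#' @param max_text_len maximum caption length in tokens.
#' @return a `qformer_config` list.
#' @export
qformer_config <- function(modality, input_dim, vocab_size,
                           num_layers = 12L, hidden_dim = 128L,
                           num_heads = 8L, ff_width = 4L * hidden_dim,
                           num_queries = NULL, cross_attn_period = 2L,
                           contrast_dim = hidden_dim, max_text_len = 48L) {
  if (is.null(num_queries)) {
    num_queries <- switch(modality, sequence = 32L, gene = 8L, protein = 8L,
                          stop("num_queries required for modality '", modality, "'"))
  }
  if (hidden_dim %% num_heads != 0L) {
    stop("hidden_dim must be divisible by num_heads")
  }
  if (cross_attn_period < 1L) stop("cross_attn_period must be >= 1")
  structure(list(modality = modality, input_dim = as.integer(input_dim),
                 vocab_size = as.integer(vocab_size),
                 num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 num_heads = as.integer(num_heads),
                 ff_width = as.integer(ff_width),
                 num_queries = as.integer(num_queries),
                 cross_attn_period = as.integer(cross_attn_period),
                 contrast_dim = as.integer(contrast_dim),
                 max_text_len = as.integer(max_text_len)),
            class = "qformer_config")
}

.qf_mat <- function(n, m, sd = 0.02) ad_param(matrix(stats::rnorm(n * m, sd = sd), n, m))
.qf_zeros <- function(m) ad_param(matrix(0, 1, m))
.qf_ones <- function(m) ad_param(matrix(1, 1, m))
.qf_attn <- function(d) list(Wq = .qf_mat(d, d), bq = .qf_zeros(d),
                             Wk = .qf_mat(d, d), bk = .qf_zeros(d),
                             Wv = .qf_mat(d, d), bv = .qf_zeros(d),
                             Wo = .qf_mat(d, d), bo = .qf_zeros(d))

#' Initialize a Q-former model
#'
#' @param config a [qformer_config()].
#' @param seed RNG seed for weight initialization.
#' @return a `qformer` object (config + `ad` parameter tree).
#' @export
qformer_init <- function(config, seed = 0L) {
  set.seed(seed)
  d <- config$hidden_dim
  layers <- lapply(seq_len(config$num_layers), function(l) {
    has_cross <- ((l - 1L) %% config$cross_attn_period) == 0L
    ly <- list(self = .qf_attn(d), ln1_g = .qf_ones(d), ln1_b = .qf_zeros(d),
               W1 = .qf_mat(d, config$ff_width), b1 = .qf_zeros(config$ff_width),
               W2 = .qf_mat(config$ff_width, d), b2 = .qf_zeros(d),
               ln2_g = .qf_ones(d), ln2_b = .qf_zeros(d))
    if (has_cross) {
      ly$cross <- .qf_attn(d)
      ly$lnc_g <- .qf_ones(d); ly$lnc_b <- .qf_zeros(d)
    }
    ly
  })
  params <- list(
    W_in = .qf_mat(config$input_dim, d, sd = 0.1), b_in = .qf_zeros(d),
    queries = .qf_mat(config$num_queries, d, sd = 0.1),
    tok_emb = .qf_mat(config$vocab_size, d, sd = 0.1),
    pos_emb = .qf_mat(config$max_text_len, d, sd = 0.05),
    layers = layers,
    lnf_g = .qf_ones(d), lnf_b = .qf_zeros(d),
    itc_q_W = .qf_mat(d, config$contrast_dim, sd = 0.1),
    itc_q_b = .qf_zeros(config$contrast_dim),
    itc_t_W = .qf_mat(d, config$contrast_dim, sd = 0.1),
    itc_t_b = .qf_zeros(config$contrast_dim),
    log_tau = ad_param(matrix(-log(14.3), 1, 1)),
    itm_W = .qf_mat(d, 2L, sd = 0.1), itm_b = .qf_zeros(2L),
    lm_W = .qf_mat(d, config$vocab_size, sd = 0.1),
    lm_b = .qf_zeros(config$vocab_size))
  structure(list(config = config, params = params), class = "qformer")
}

#' Collect trainable parameters from a model object
#' @param x a model (`qformer`, `master_qformer`) or nested list of `ad`.
#' @return flat list of `ad` parameter nodes.
#' @export
vq_parameters <- function(x) {
  out <- list()
  walk <- function(node) {
    if (ad_is(node)) {
      if (node$requires) out[[length(out) + 1L]] <<- node
    } else if (is.list(node)) {
      for (el in node) walk(el)
    }
  }
  walk(if (is.list(x) && !is.null(x$params)) x$params else x)
  out
}

#' Deep-copy a model
#'
#' Parameters live in mutable `ad` environments; cloning gives an
#' independent copy (e.g. to train two variants from identical weights).
#'
#' @param model a `qformer`, `master_qformer` or any nested `ad` structure.
#' @export
vq_clone <- function(model) {
  copy <- function(node) {
    if (ad_is(node)) return(ad_tensor(node$val, requires_grad = node$requires))
    if (is.list(node) && is.null(attr(node, "class"))) return(lapply(node, copy))
    node
  }
  if (is.list(model) && !is.null(model$params)) {
    model$params <- copy(model$params)
    model
  } else copy(model)
}

# text token embeddings (+positions) as an ad node
.qf_text_embed <- function(model, text_ids) {
  p <- model$params
  T_ <- length(text_ids)
  stopifnot(T_ >= 1L, T_ <= model$config$max_text_len)
  ad_add(ad_rows(p$tok_emb, as.integer(text_ids)),
         ad_rows(p$pos_emb, seq_len(T_)))
}

# joint-mask construction; K query rows then T text rows
.qf_mask <- function(mode, K, T_) {
  n <- K + T_
  m <- matrix(0, n, n)
  if (mode == "itc") {
    if (K > 0L && T_ > 0L) {
      m[seq_len(K), K + seq_len(T_)] <- -1e9
      m[K + seq_len(T_), seq_len(K)] <- -1e9
    }
  } else if (mode == "itg") {
    if (K > 0L && T_ > 0L) m[seq_len(K), K + seq_len(T_)] <- -1e9
    if (T_ > 1L) {
      tt <- matrix(-1e9, T_, T_)
      tt[lower.tri(tt, diag = TRUE)] <- 0
      m[K + seq_len(T_), K + seq_len(T_)] <- tt
    }
  }
  m  # "itm": fully bidirectional
}

# shared transformer trunk. Returns final hidden states (ad node).
# embedding: numeric matrix or NULL; text_ids: integer or NULL.
.qf_forward <- function(model, embedding = NULL, text_ids = NULL,
                        mode = c("queries", "text", "itm", "itg")) {
  mode <- match.arg(mode)
  cfg <- model$config
  p <- model$params
  use_queries <- mode != "text"
  K <- if (use_queries) cfg$num_queries else 0L
  T_ <- if (is.null(text_ids)) 0L else length(text_ids)
  enc <- NULL
  if (use_queries) {
    if (is.null(embedding)) stop("modality embedding required in mode '", mode, "'")
    if (ncol(embedding) != cfg$input_dim) {
      stop(sprintf("embedding dimension mismatch for modality '%s': expected %d, got %d",
                   cfg$modality, cfg$input_dim, ncol(embedding)))
    }
    enc <- ad_linear(ad_const(unclass(embedding)), p$W_in, p$b_in)
  }
  parts <- list()
  if (K > 0L) parts <- c(parts, list(p$queries))
  if (T_ > 0L) parts <- c(parts, list(.qf_text_embed(model, text_ids)))
  stopifnot(length(parts) > 0L)
  x <- if (length(parts) == 1L) parts[[1L]] else ad_rbind(parts)
  mask <- if (K > 0L && T_ > 0L) {
    .qf_mask(if (mode == "queries") "itm" else mode, K, T_)
  } else if (mode == "itg" && T_ > 1L) {
    .qf_mask("itg", 0L, T_)
  } else NULL
  for (li in seq_len(cfg$num_layers)) {
    ly <- p$layers[[li]]
    h <- ad_layernorm(x, ly$ln1_g, ly$ln1_b)
    x <- ad_add(x, ad_mha(h, h, ly$self$Wq, ly$self$bq, ly$self$Wk, ly$self$bk,
                          ly$self$Wv, ly$self$bv, ly$self$Wo, ly$self$bo,
                          n_heads = cfg$num_heads, mask = mask))
    if (!is.null(ly$cross) && K > 0L) {
      h <- ad_layernorm(x, ly$lnc_g, ly$lnc_b)
      qrows <- if (T_ > 0L) ad_rows(h, seq_len(K)) else h
      co <- ad_mha(qrows, enc, ly$cross$Wq, ly$cross$bq, ly$cross$Wk,
                   ly$cross$bk, ly$cross$Wv, ly$cross$bv, ly$cross$Wo,
                   ly$cross$bo, n_heads = cfg$num_heads)
      delta <- if (T_ > 0L) {
        ad_rbind(list(co, ad_const(matrix(0, T_, cfg$hidden_dim))))
      } else co
      x <- ad_add(x, delta)
    }
    h <- ad_layernorm(x, ly$ln2_g, ly$ln2_b)
    x <- ad_add(x, ad_linear(ad_gelu(ad_linear(h, ly$W1, ly$b1)), ly$W2, ly$b2))
  }
  ad_layernorm(x, p$lnf_g, p$lnf_b)
}

#' Distill a modality embedding into K query tokens
#'
#' Runs the Q-former in query-only mode: the K learned queries self-attend
#' and cross-attend to the (projected) input embedding on every
#' `cross_attn_period`-th layer, yielding exactly K output tokens of width
#' `hidden_dim` regardless of the input length.
#'
#' @param model a [qformer_init()] model.
#' @param embedding numeric matrix (tokens x input_dim).
#' @param graph return the `ad` node (for training) instead of a plain
#'   matrix.
#' @return K x hidden_dim matrix (or `ad` node when `graph = TRUE`).
#' @export
encode_modality <- function(model, embedding, graph = FALSE) {
  out <- .qf_forward(model, embedding = embedding, mode = "queries")
  if (graph) out else ad_val(out)
}

#' Contrastive alignment (ITC) loss
#'
#' Symmetric in-batch InfoNCE between l2-normalized query and caption
#' projections, with a learnable temperature. Per-pair similarity is the
#' maximum cosine similarity over the K query tokens against the pooled
#' caption projection.
#'
#' @param model a `qformer`.
#' @param batch list with `embeddings` (list of matrices) and `texts` (list
#'   of integer token-id vectors), paired by index.
#' @return list: `loss` (scalar `ad` node), `sim` (B x B numeric matrix of
#'   temperature-scaled similarities, rows = embeddings, cols = captions).
#' @export
itc_loss <- function(model, batch) {
  B <- length(batch$embeddings)
  if (B < 1L || length(batch$texts) != B) {
    stop("batch must contain equally many embeddings and captions (>= 1)")
  }
  K <- model$config$num_queries
  p <- model$params
  qs <- lapply(batch$embeddings, function(e) {
    ad_l2norm_rows(ad_linear(
      .qf_forward(model, embedding = e, mode = "queries"),
      p$itc_q_W, p$itc_q_b))
  })
  ts <- lapply(batch$texts, function(ids) {
    ad_l2norm_rows(ad_linear(
      ad_mean_rows(.qf_forward(model, text_ids = ids, mode = "text")),
      p$itc_t_W, p$itc_t_b))
  })
  Qall <- if (B == 1L) qs[[1L]] else ad_rbind(qs)
  Tall <- if (B == 1L) ts[[1L]] else ad_rbind(ts)
  sim <- ad_blockmax(ad_mm(Qall, ad_t(Tall)), K)
  z <- ad_scalar_mul(sim, ad_exp(ad_scale(p$log_tau, -1)))
  diag_idx <- seq_len(B)
  loss <- ad_scale(ad_add(ad_ce_rows(z, diag_idx),
                          ad_ce_rows(ad_t(z), diag_idx)), 0.5)
  list(loss = loss, sim = ad_val(z))
}

#' Mine hard negatives from an in-batch similarity matrix
#'
#' For each item, samples one caption-negative (row-wise) and one
#' embedding-negative (column-wise) with probability proportional to the
#' softmax of off-diagonal similarities; the diagonal (the positives) is
#' excluded.
#'
#' @param sim square B x B similarity matrix, diagonal = positive pairs.
#' @return data frame with columns `item`, `text_neg`, `emb_neg`; zero rows
#'   (with a warning) when B = 1.
#' @export
mine_hard_negatives <- function(sim) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  B <- nrow(sim)
  if (B < 2L) {
    warning("batch of size 1: no negatives available")
    return(data.frame(item = integer(), text_neg = integer(),
                      emb_neg = integer()))
  }
  pick <- function(scores, self) {
    idx <- setdiff(seq_len(B), self)
    w <- exp(scores[idx] - max(scores[idx]))
    idx[sample.int(length(idx), 1L, prob = w / sum(w))]
  }
  data.frame(
    item = seq_len(B),
    text_neg = vapply(seq_len(B), function(i) pick(sim[i, ], i), integer(1)),
    emb_neg = vapply(seq_len(B), function(i) pick(sim[, i], i), integer(1)))
}

#' Matching (ITM) loss
#'
#' Joint forward with caption cross-attention enabled (fully bidirectional
#' query/text attention); mean-pooled query outputs feed a two-way head and
#' the mean cross-entropy over match labels is returned.
#'
#' @param model a `qformer`.
#' @param pairs list of `list(embedding, text_ids, match)` items.
#' @return list: `loss` (scalar `ad` node), `logits` (n x 2 numeric).
#' @export
itm_loss <- function(model, pairs) {
  if (length(pairs) < 1L) stop("itm_loss needs at least one pair")
  K <- model$config$num_queries
  p <- model$params
  logit_nodes <- lapply(pairs, function(pr) {
    h <- .qf_forward(model, embedding = pr$embedding,
                     text_ids = pr$text_ids, mode = "itm")
    ad_linear(ad_mean_rows(ad_rows(h, seq_len(K))), p$itm_W, p$itm_b)
  })
  logits <- if (length(logit_nodes) == 1L) logit_nodes[[1L]] else ad_rbind(logit_nodes)
  targets <- ifelse(vapply(pairs, function(pr) isTRUE(pr$match), logical(1)), 2L, 1L)
  list(loss = ad_ce_rows(logits, targets), logits = ad_val(logits))
}

#' Build ITM pairs from mined negatives
#'
#' Per batch item: one positive, one mined caption-negative, one mined
#' embedding-negative.
#'
#' @param batch as in [itc_loss()].
#' @param negs data frame from [mine_hard_negatives()].
#' @export
itm_pairs <- function(batch, negs) {
  out <- list()
  for (i in seq_len(length(batch$embeddings))) {
    out[[length(out) + 1L]] <- list(embedding = batch$embeddings[[i]],
                                    text_ids = batch$texts[[i]], match = TRUE)
    row <- which(negs$item == i)
    if (length(row) == 1L) {
      out[[length(out) + 1L]] <- list(embedding = batch$embeddings[[i]],
                                      text_ids = batch$texts[[negs$text_neg[row]]],
                                      match = FALSE)
      out[[length(out) + 1L]] <- list(embedding = batch$embeddings[[negs$emb_neg[row]]],
                                      text_ids = batch$texts[[i]], match = FALSE)
    }
  }
  out
}

#' Grounded caption-generation (ITG) loss
#'
#' Causal language modeling of the caption with the query tokens visible to
#' every text position (text self-attention causally masked, queries blind to
#' text). Mean per-token cross-entropy; the caption is framed by BOS/EOS.
#'
#' @param model a `qformer`.
#' @param embedding modality embedding matrix.
#' @param text_ids integer caption token ids (non-empty).
#' @param bos_id,eos_id sentence-marker token ids.
#' @return list: `loss` (scalar `ad` node).
#' @export
itg_loss <- function(model, embedding, text_ids, bos_id = 2L, eos_id = 3L) {
  if (length(text_ids) < 1L) stop("itg_loss: caption must be non-empty")
  K <- model$config$num_queries
  inp <- c(bos_id, as.integer(text_ids))
  labels <- c(as.integer(text_ids), eos_id)
  h <- .qf_forward(model, embedding = embedding, text_ids = inp, mode = "itg")
  text_h <- ad_rows(h, K + seq_along(inp))
  logits <- ad_linear(text_h, model$params$lm_W, model$params$lm_b)
  list(loss = ad_ce_rows(logits, labels), logits = ad_val(logits),
       labels = labels)
}

#' Total Stage-1 loss across modalities
#'
#' Plain unweighted sum of the per-modality (ITC, ITM, ITG) triples.
#'
#' @param per_modality_losses list (length N >= 1) of length-3 lists or
#'   numeric vectors; elements may be scalar `ad` nodes or plain numbers.
#' @return scalar `ad` node if any input is one, else a number.
#' @export
stage1_total_loss <- function(per_modality_losses) {
  if (length(per_modality_losses) < 1L) stop("need at least one modality")
  flat <- unlist(lapply(per_modality_losses, function(x) {
    if (ad_is(x)) list(x) else as.list(x)
  }), recursive = FALSE)
  if (any(vapply(flat, ad_is, logical(1)))) {
    ad_sum_scalars(lapply(flat, function(x) if (ad_is(x)) x else ad_const(matrix(x, 1, 1))))
  } else {
    sum(unlist(flat))
  }
}

#' In-batch retrieval accuracy from a similarity matrix
#'
#' Fraction of rows whose argmax lies on the diagonal (embedding -> caption
#' retrieval).
#'
#' @param sim square similarity matrix.
#' @export
in_batch_retrieval <- function(sim) {
  mean(max.col(sim, ties.method = "first") == seq_len(nrow(sim)))
}
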