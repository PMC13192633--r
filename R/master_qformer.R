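# Master fusion Q-former.
#
# Stage-2 model: N_m learned meta-queries are concatenated with the
# tokenized instruction into one sequence that self-attends jointly; on
# every `cross_attn_period`-th layer the meta-query positions cross-attend
# to the layer-normalised concatenation of all Stage-1 modality tokens.
# Only the meta-query positions are emitted and projected (W_proj) into the
# frozen decoder's embedding space, giving a fixed-length multimodal prefix.

#' Master Q-former configuration
#'
#' Defaults follow the fusion model: 6 layers, 32 meta-queries,
#' cross-attention every 2 layers, hidden width equal to the Stage-1 width
#' so no adapter is needed between stages.
#'
#' @param decoder_dim token-embedding width of the attached decoder (the
#'   projection target).
#' @param instr_vocab_size instruction vocabulary size.
#' @param num_layers,n_meta,cross_attn_period,hidden_dim,num_heads
#'   architecture knobs.
#' @param max_instr_len maximum instruction length.
#' @export
master_config <- function(decoder_dim, instr_vocab_size, num_layers = 6L,
                          n_meta = 32L, cross_attn_period = 2L,
                          hidden_dim = 128L, num_heads = 8L,
                          max_instr_len = 64L) {
  if (hidden_dim %% num_heads != 0L) stop("hidden_dim must be divisible by num_heads")
  if (cross_attn_period < 1L) stop("cross_attn_period must be >= 1")
  structure(list(decoder_dim = as.integer(decoder_dim),
                 instr_vocab_size = as.integer(instr_vocab_size),
                 num_layers = as.integer(num_layers),
                 n_meta = as.integer(n_meta),
                 cross_attn_period = as.integer(cross_attn_period),
                 hidden_dim = as.integer(hidden_dim),
                 num_heads = as.integer(num_heads),
                 max_instr_len = as.integer(max_instr_len)),
            class = "master_config")
}

#' Initialize the master Q-former
#'
#' @param config a [master_config()].
#' @param seed RNG seed.
#' @return a `master_qformer` object.
#' @export
master_init <- function(config, seed = 0L) {
  set.seed(seed)
  d <- config$hidden_dim
  layers <- lapply(seq_len(config$num_layers), function(l) {
    ly <- list(self = .qf_attn(d), ln1_g = .qf_ones(d), ln1_b = .qf_zeros(d),
               W1 = .qf_mat(d, 4L * d), b1 = .qf_zeros(4L * d),
               W2 = .qf_mat(4L * d, d), b2 = .qf_zeros(d),
               ln2_g = .qf_ones(d), ln2_b = .qf_zeros(d))
    if (((l - 1L) %% config$cross_attn_period) == 0L) {
      ly$cross <- .qf_attn(d)
      ly$lnc_g <- .qf_ones(d); ly$lnc_b <- .qf_zeros(d)
      ly$lnkv_g <- .qf_ones(d); ly$lnkv_b <- .qf_zeros(d)
    }
    ly
  })
  params <- list(
    meta_queries = .qf_mat(config$n_meta, d, sd = 0.1),
    instr_emb = .qf_mat(config$instr_vocab_size, d, sd = 0.1),
    instr_pos = .qf_mat(config$max_instr_len, d, sd = 0.05),
    layers = layers,
    lnf_g = .qf_ones(d), lnf_b = .qf_zeros(d),
    W_proj = .qf_mat(d, config$decoder_dim, sd = 0.1),
    b_proj = .qf_zeros(config$decoder_dim))
  structure(list(config = config, params = params), class = "master_qformer")
}

#' Fuse modality tokens and an instruction into the multimodal prefix
#'
#' @param master a [master_init()] model.
#' @param modality_tokens non-empty list of Stage-1 query-token matrices (or
#'   `ad` nodes), each K_i x hidden_dim; concatenated along the token axis in
#'   the given order and layer-normalised before every cross-attention.
#' @param instr_ids integer instruction token ids (may be empty).
#' @param graph return the `ad` node (training) instead of a matrix.
#' @return `n_meta` x decoder_dim prefix (matrix, or `ad` node), carrying the
#'   contributing modality names as the `provenance` attribute when numeric.
#' @export
fuse <- function(master, modality_tokens, instr_ids = integer(), graph = FALSE) {
  cfg <- master$config
  p <- master$params
  if (length(modality_tokens) < 1L) stop("fuse: need at least one modality token set")
  toks <- lapply(modality_tokens, function(m) if (ad_is(m)) m else ad_const(m))
  for (m in toks) {
    if (ncol(ad_val(m)) != cfg$hidden_dim) {
      stop(sprintf("fuse: modality token width %d != hidden_dim %d",
                   ncol(ad_val(m)), cfg$hidden_dim))
    }
  }
  vis <- if (length(toks) == 1L) toks[[1L]] else ad_rbind(toks)
  N <- cfg$n_meta
  T_ <- length(instr_ids)
  x <- p$meta_queries
  if (T_ > 0L) {
    stopifnot(T_ <= cfg$max_instr_len)
    instr <- ad_add(ad_rows(p$instr_emb, as.integer(instr_ids)),
                    ad_rows(p$instr_pos, seq_len(T_)))
    x <- ad_rbind(list(x, instr))
  }
  for (li in seq_len(cfg$num_layers)) {
    ly <- p$layers[[li]]
    h <- ad_layernorm(x, ly$ln1_g, ly$ln1_b)
    x <- ad_add(x, ad_mha(h, h, ly$self$Wq, ly$self$bq, ly$self$Wk, ly$self$bk,
                          ly$self$Wv, ly$self$bv, ly$self$Wo, ly$self$bo,
                          n_heads = cfg$num_heads))
    if (!is.null(ly$cross)) {
      kv <- ad_layernorm(vis, ly$lnkv_g, ly$lnkv_b)
      h <- ad_layernorm(x, ly$lnc_g, ly$lnc_b)
      qrows <- if (T_ > 0L) ad_rows(h, seq_len(N)) else h
      co <- ad_mha(qrows, kv, ly$cross$Wq, ly$cross$bq, ly$cross$Wk,
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
  x <- ad_layernorm(x, p$lnf_g, p$lnf_b)
  meta_out <- if (T_ > 0L) ad_rows(x, seq_len(N)) else x
  prefix <- ad_linear(meta_out, p$W_proj, p$b_proj)
  if (graph) return(prefix)
  out <- ad_val(prefix)
  attr(out, "provenance") <- names(modality_tokens) %||% seq_along(modality_tokens)
  out
}

#' Assemble decoder input and loss mask
#'
#' Input order is prefix, prompt, answer. Labels follow the ignore-index
#' convention: `NA` (the -100 analogue) at every prefix and prompt position,
#' the token id at answer positions; next-token loss later shifts these
#' internally.
#'
#' @param prefix multimodal prefix (matrix or `ad` node).
#' @param prompt_ids,answer_ids integer token ids; `answer_ids` may be empty
#'   (inference mode: zero unmasked labels).
#' @return list: `prefix`, `tokens` (prompt then answer), `labels` (length
#'   n_prefix + n_tokens, NA where masked).
#' @export
assemble_decoder_input <- function(prefix, prompt_ids, answer_ids = integer()) {
  stopifnot(!is.null(prefix))
  n_pre <- nrow(ad_val(prefix))
  tokens <- c(as.integer(prompt_ids), as.integer(answer_ids))
  labels <- rep(NA_integer_, n_pre + length(tokens))
  if (length(answer_ids) > 0L) {
    labels[n_pre + length(prompt_ids) + seq_along(answer_ids)] <-
      as.integer(answer_ids)
  }
  list(prefix = prefix, tokens = tokens, labels = labels)
}

#' Next-token-prediction loss over assembled decoder input
#'
#' Cross-entropy between the decoder's logits at positions 1..L-1 and the
#' labels at positions 2..L; masked (NA) labels contribute nothing.
#'
#' @param decoder a [tiny_frozen_decoder()].
#' @param assembled output of [assemble_decoder_input()].
#' @return list: `loss` (scalar `ad` node), `n_supervised` (unmasked count).
#' @export
ntp_loss <- function(decoder, assembled) {
  logits <- decoder_forward(decoder, assembled$tokens, prefix = assembled$prefix)
  L <- nrow(ad_val(logits))
  shifted <- assembled$labels[-1L]
  loss <- ad_ce_rows(ad_rows(logits, seq_len(L - 1L)), shifted)
  list(loss = loss, n_supervised = sum(!is.na(shifted)))
}
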