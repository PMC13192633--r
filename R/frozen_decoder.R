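# Tiny frozen causal text decoder.
#
# Stands in for the frozen LLM backbone: a small causal transformer language
# model with seed-determined, non-trainable weights. Forward passes wrap the
# weights as constants, so gradients flow through the decoder to a prepended
# continuous prefix (and onward to the fusion stack) but never into the
# decoder itself.

.dec_init_mat <- function(n, m, sd = 0.2) matrix(stats::rnorm(n * m, sd = sd), n, m)

#' Construct a tiny frozen causal decoder
#'
#' @param vocab_size token vocabulary size (>= 8).
#' @param dim token embedding / hidden dimension.
#' @param seed RNG seed; equal seeds give identical weights.
#' @param n_layers,n_heads transformer depth and heads.
#' @param max_len maximum total sequence length (prefix + text).
#' @return a `frozen_decoder`: list with `params` (plain numeric matrices),
#'   `vocab_size`, `dim`, `frozen = TRUE`.
#' @export
tiny_frozen_decoder <- function(vocab_size, dim = 32L, seed = 0L,
                                n_layers = 2L, n_heads = 2L, max_len = 64L) {
  if (vocab_size < 8L) stop("vocab_size must be >= 8")
  stopifnot(dim %% n_heads == 0L)
  set.seed(seed)
  mk_attn <- function() list(
    Wq = .dec_init_mat(dim, dim), bq = matrix(0, 1, dim),
    Wk = .dec_init_mat(dim, dim), bk = matrix(0, 1, dim),
    Wv = .dec_init_mat(dim, dim), bv = matrix(0, 1, dim),
    Wo = .dec_init_mat(dim, dim), bo = matrix(0, 1, dim))
  layers <- lapply(seq_len(n_layers), function(l) list(
    attn = mk_attn(),
    ln1_g = matrix(1, 1, dim), ln1_b = matrix(0, 1, dim),
    W1 = .dec_init_mat(dim, 4L * dim), b1 = matrix(0, 1, 4L * dim),
    W2 = .dec_init_mat(4L * dim, dim, sd = 0.1), b2 = matrix(0, 1, dim),
    ln2_g = matrix(1, 1, dim), ln2_b = matrix(0, 1, dim)))
  params <- list(
    tok_emb = .dec_init_mat(vocab_size, dim, sd = 0.5),
    pos_emb = .dec_init_mat(max_len, dim, sd = 0.3),
    layers = layers,
    lnf_g = matrix(1, 1, dim), lnf_b = matrix(0, 1, dim),
    W_out = .dec_init_mat(dim, vocab_size, sd = 0.3),
    b_out = matrix(0, 1, vocab_size))
  structure(list(params = params, vocab_size = as.integer(vocab_size),
                 dim = as.integer(dim), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), max_len = as.integer(max_len),
                 frozen = TRUE),
            class = "frozen_decoder")
}

#' Decoder forward pass
#'
#' Embeds `token_ids`, prepends the continuous `prefix` (if any), runs the
#' causally masked transformer and returns next-token logits at every
#' position. Decoder weights enter the graph as constants; gradients reach
#' only the prefix.
#'
#' @param decoder a [tiny_frozen_decoder()].
#' @param token_ids integer token ids (may be empty).
#' @param prefix optional prefix: an `ad` node or numeric matrix
#'   (n_prefix x dim).
#' @return `ad` node of logits ((n_prefix + n_tokens) x vocab).
#' @export
decoder_forward <- function(decoder, token_ids, prefix = NULL) {
  p <- decoder$params
  n_pre <- if (is.null(prefix)) 0L else nrow(ad_val(prefix))
  n_tok <- length(token_ids)
  L <- n_pre + n_tok
  stopifnot(L >= 1L, L <= decoder$max_len)
  parts <- list()
  if (n_pre > 0L) {
    if (!ad_is(prefix)) prefix <- ad_const(prefix)
    parts <- c(parts, list(prefix))
  }
  if (n_tok > 0L) {
    tok <- p$tok_emb[token_ids, , drop = FALSE] +
      p$pos_emb[n_pre + seq_len(n_tok), , drop = FALSE]
    parts <- c(parts, list(ad_const(tok)))
  }
  x <- if (length(parts) == 1L) parts[[1L]] else ad_rbind(parts)
  if (n_pre > 0L) {
    # prefix rows get their positional code additively, keeping grad flow
    x <- ad_add(x, ad_const(rbind(
      p$pos_emb[seq_len(n_pre), , drop = FALSE],
      matrix(0, n_tok, decoder$dim))))
  }
  mask <- matrix(-1e9, L, L)
  mask[lower.tri(mask, diag = TRUE)] <- 0
  for (ly in p$layers) {
    h <- ad_layernorm(x, ad_const(ly$ln1_g), ad_const(ly$ln1_b))
    a <- ly$attn
    x <- ad_add(x, ad_mha(h, h, ad_const(a$Wq), ad_const(a$bq),
                          ad_const(a$Wk), ad_const(a$bk),
                          ad_const(a$Wv), ad_const(a$bv),
                          ad_const(a$Wo), ad_const(a$bo),
                          n_heads = decoder$n_heads, mask = mask))
    h <- ad_layernorm(x, ad_const(ly$ln2_g), ad_const(ly$ln2_b))
    ff <- ad_linear(ad_gelu(ad_linear(h, ad_const(ly$W1), ad_const(ly$b1))),
                    ad_const(ly$W2), ad_const(ly$b2))
    x <- ad_add(x, ff)
  }
  x <- ad_layernorm(x, ad_const(p$lnf_g), ad_const(p$lnf_b))
  ad_linear(x, ad_const(p$W_out), ad_const(p$b_out))
}

#' Greedy decoding under a fixed prefix
#'
#' @param decoder a [tiny_frozen_decoder()].
#' @param prefix numeric matrix or `ad` node (or NULL).
#' @param prompt_ids integer prompt token ids.
#' @param max_new_tokens number of tokens to generate.
#' @param stop_ids token ids that end generation when emitted.
#' @return integer vector of generated token ids.
#' @export
greedy_decode <- function(decoder, prefix, prompt_ids, max_new_tokens = 8L,
                          stop_ids = integer()) {
  ids <- as.integer(prompt_ids)
  out <- integer()
  pref_val <- if (is.null(prefix)) NULL else ad_val(prefix)
  for (i in seq_len(max_new_tokens)) {
    n_pre <- if (is.null(pref_val)) 0L else nrow(pref_val)
    if (n_pre + length(ids) + 1L > decoder$max_len) break
    logits <- ad_val(decoder_forward(decoder, ids, prefix = pref_val))
    nxt <- which.max(logits[nrow(logits), ])
    if (nxt %in% stop_ids) break
    out <- c(out, nxt)
    ids <- c(ids, nxt)
  }
  out
}

#' Checksum of decoder weights (frozen-contract probe)
#' @param decoder a [tiny_frozen_decoder()].
#' @return numeric scalar; changes iff any weight bit changes.
#' @export
decoder_checksum <- function(decoder) {
  flat <- unlist(decoder$params, use.names = FALSE)
  sum(flat * seq_along(flat)) + sum(flat^2)
}
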