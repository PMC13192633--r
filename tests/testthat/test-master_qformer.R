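# Master fusion model: fixed-length prefix contract, instruction
# sensitivity, decoder-input assembly and loss masking.

tiny_master <- function(decoder_dim = 12L, seed = 2L) {
  master_init(master_config(decoder_dim = decoder_dim, instr_vocab_size = 40L,
                            num_layers = 2L, hidden_dim = 16L, num_heads = 4L,
                            n_meta = 32L),
              seed = seed)
}

mk_tokens <- function(ks = c(sequence = 6L, gene = 4L, protein = 2L), d = 16L) {
  set.seed(1)
  lapply(ks, function(k) matrix(stats::rnorm(k * d), k))
}

test_that("fuse emits exactly 32 prefix vectors for any modality subset", {
  m <- tiny_master()
  toks <- mk_tokens()
  for (sub in list(1L, 1:2, 1:3)) {
    pre <- fuse(m, toks[sub], instr_ids = c(4L, 9L))
    expect_equal(dim(pre), c(32L, 12L))
  }
  # emitted count independent of instruction length
  for (ilen in c(0L, 4L, 64L)) {
    ids <- if (ilen > 0L) rep(3L, ilen) else integer()
    expect_equal(nrow(fuse(m, toks, instr_ids = ids)), 32L)
  }
  expect_error(fuse(m, list()), "at least one modality")
  expect_error(fuse(m, list(matrix(0, 4, 9))), "hidden_dim")
})

test_that("the prefix is sensitive to the instruction and projects to decoder space", {
  m <- tiny_master()
  toks <- mk_tokens()
  a <- fuse(m, toks, instr_ids = c(4L, 9L, 11L))
  b <- fuse(m, toks, instr_ids = c(4L, 10L, 11L))  # one token changed
  expect_gt(max(abs(a - b)), 1e-8)
  dec <- tiny_frozen_decoder(64L, dim = 12L, seed = 0)
  expect_equal(ncol(a), dec$dim)
  expect_equal(attr(a, "provenance"), c("sequence", "gene", "protein"))
})

test_that("every cross-attention layer normalises the visual tokens first", {
  m <- tiny_master()
  for (ly in m$params$layers) {
    if (!is.null(ly$cross)) {
      expect_false(is.null(ly$lnkv_g))
      expect_false(is.null(ly$lnkv_b))
    }
  }
  # cross-attention sits on 0-based even layers
  has_cross <- vapply(m$params$layers, function(ly) !is.null(ly$cross), logical(1))
  expect_equal(which(has_cross), seq(1L, m$config$num_layers, by = 2L))
})

test_that("decoder input assembly masks prefix and prompt positions", {
  prefix <- matrix(0, 32, 12)
  asm <- assemble_decoder_input(prefix, prompt_ids = 1:5, answer_ids = 6:8)
  expect_length(asm$tokens, 8L)  # 8 text positions
  expect_equal(sum(!is.na(asm$labels)), 3L)
  expect_equal(asm$labels[32L + 5L + 1:3], 6:8)
  # inference mode: empty answer, zero unmasked labels
  asm0 <- assemble_decoder_input(prefix, prompt_ids = 1:5)
  expect_equal(sum(!is.na(asm0$labels)), 0L)
})

test_that("NTP loss ignores masked labels (perturbation leaves it unchanged)", {
  dec <- tiny_frozen_decoder(32L, dim = 12L, seed = 1)
  m <- tiny_master()
  pre <- fuse(m, mk_tokens(), instr_ids = c(2L, 3L))
  asm <- assemble_decoder_input(pre, prompt_ids = c(4L, 5L, 6L),
                                answer_ids = c(7L, 8L))
  base <- as.numeric(ad_val(ntp_loss(dec, asm)$loss))
  expect_equal(ntp_loss(dec, asm)$n_supervised, 2L)
  # masking oracle: the loss equals the cross-entropy at the answer
  # positions alone, computed directly from the decoder's logits
  logits <- ad_val(decoder_forward(dec, asm$tokens, prefix = pre))
  ce_at <- function(pos, tok) {
    z <- logits[pos, ]
    -log(exp(z[tok]) / sum(exp(z)))
  }
  # answers at text positions 4 and 5 are predicted from the previous slot
  oracle <- mean(c(ce_at(32L + 3L, 7L), ce_at(32L + 4L, 8L)))
  expect_equal(base, oracle, tolerance = 1e-8)
  # swapping the prompt for a different one changes supervision only via
  # the forward pass; extending the answer adds supervised positions
  asm3 <- assemble_decoder_input(pre, prompt_ids = c(4L, 5L, 6L),
                                 answer_ids = c(7L, 8L, 9L))
  expect_equal(ntp_loss(dec, asm3)$n_supervised, 3L)
})
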