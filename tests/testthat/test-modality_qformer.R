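# Q-former contracts and the three alignment losses.

tiny_qf <- function(modality = "gene", input_dim = 6L, vocab_size = 32L,
                    num_queries = NULL, seed = 1L) {
  cfg <- qformer_config(modality, input_dim = input_dim,
                        vocab_size = vocab_size, num_layers = 2L,
                        hidden_dim = 16L, num_heads = 4L,
                        num_queries = num_queries, contrast_dim = 8L)
  qformer_init(cfg, seed = seed)
}

tiny_batch <- function(model, B, len = 5L, seed = 9L) {
  set.seed(seed)
  d <- model$config$input_dim
  list(embeddings = replicate(B, matrix(stats::rnorm(len * d), len), simplify = FALSE),
       texts = replicate(B, sample.int(model$config$vocab_size, 6L), simplify = FALSE))
}

test_that("encode_modality emits exactly K tokens for any input length", {
  m <- tiny_qf()
  for (len in c(1L, 16L, 512L)) {
    out <- encode_modality(m, matrix(stats::rnorm(len * 6), len))
    expect_equal(dim(out), c(8L, 16L))  # gene modality: K = 8
  }
  seq_m <- tiny_qf("sequence", input_dim = 4L)
  expect_equal(nrow(encode_modality(seq_m, matrix(0, 10, 4))), 32L)
  x <- matrix(stats::rnorm(12 * 6), 12)
  expect_identical(encode_modality(m, x), encode_modality(m, x))
  expect_error(encode_modality(m, matrix(0, 3, 5)),
               "expected 6, got 5")
})

test_that("ITC loss hits its closed-form limits and the direct formula", {
  m <- tiny_qf()
  b1 <- tiny_batch(m, 1L)
  expect_lt(abs(as.numeric(ad_val(itc_loss(m, b1)$loss))), 1e-6)
  # identical pairs: uniform softmax -> log B
  b4 <- list(embeddings = rep(b1$embeddings, 4L), texts = rep(b1$texts, 4L))
  expect_lt(abs(as.numeric(ad_val(itc_loss(m, b4)$loss)) - log(4)), 1e-6)
  # direct arithmetic evaluation of the symmetric InfoNCE from the model's
  # own normalized projections (independent of the loss code path)
  b2 <- tiny_batch(m, 2L)
  p <- m$params
  l2 <- function(v) v / sqrt(sum(v^2))
  qhat <- lapply(b2$embeddings, function(e) {
    q <- encode_modality(m, e) %*% ad_val(p$itc_q_W) +
      matrix(ad_val(p$itc_q_b), 8L, 8L, byrow = TRUE)
    t(apply(q, 1L, l2))
  })
  that <- lapply(b2$texts, function(ids) {
    h <- ad_val(varqform:::.qf_forward(m, text_ids = ids, mode = "text"))
    l2(colMeans(h) %*% ad_val(p$itc_t_W) + as.numeric(ad_val(p$itc_t_b)))
  })
  S <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) S[i, j] <- max(qhat[[i]] %*% t(that[[j]]))
  S <- S / exp(as.numeric(ad_val(p$log_tau)))
  ce <- function(M) mean(-log(exp(diag(M)) / rowSums(exp(M))))
  oracle <- 0.5 * (ce(S) + ce(t(S)))
  expect_equal(as.numeric(ad_val(itc_loss(m, b2)$loss)), oracle,
               tolerance = 1e-8)
  # symmetry: both softmax directions weighted equally
  sim <- itc_loss(m, b2)$sim
  expect_equal(0.5 * (ce(sim) + ce(t(sim))),
               as.numeric(ad_val(itc_loss(m, b2)$loss)), tolerance = 1e-8)
})

test_that("hard-negative mining follows the softmax weights and skips the diagonal", {
  # B = 2: the only candidate is the other item
  negs <- mine_hard_negatives(matrix(c(1, 0, 0, 1), 2))
  expect_equal(negs$text_neg, c(2L, 1L))
  expect_equal(negs$emb_neg, c(2L, 1L))
  expect_warning(none <- mine_hard_negatives(matrix(1, 1, 1)), "size 1")
  expect_equal(nrow(none), 0L)
  # a dominating off-diagonal entry (softmax weight > 0.99) wins > 95%
  sim <- matrix(0, 3, 3)
  sim[1, 2] <- 10  # vs sim[1, 3] = 0
  set.seed(4)
  draws <- replicate(1000, mine_hard_negatives(sim)$text_neg[1])
  expect_gt(mean(draws == 2L), 0.95)
  expect_true(all(draws != 1L))  # diagonal never selected
})

test_that("ITM loss matches BCE closed forms on the real forward path", {
  m <- tiny_qf()
  b <- tiny_batch(m, 2L)
  pairs <- list(
    list(embedding = b$embeddings[[1]], text_ids = b$texts[[1]], match = TRUE),
    list(embedding = b$embeddings[[1]], text_ids = b$texts[[2]], match = FALSE),
    list(embedding = b$embeddings[[2]], text_ids = b$texts[[2]], match = TRUE))
  # zeroed head -> logits all zero -> ln 2 exactly
  m$params$itm_W$val[] <- 0
  m$params$itm_b$val[] <- 0
  expect_lt(abs(as.numeric(ad_val(itm_loss(m, pairs)$loss)) - log(2)), 1e-6)
  # hand-computed mean BCE from whatever logits the head emits
  m2 <- tiny_qf(seed = 5L)
  out <- itm_loss(m2, pairs)
  lg <- out$logits
  tgt <- c(2L, 1L, 2L)
  oracle <- mean(vapply(1:3, function(i) {
    -log(exp(lg[i, tgt[i]]) / sum(exp(lg[i, ])))
  }, numeric(1)))
  expect_equal(as.numeric(ad_val(out$loss)), oracle, tolerance = 1e-8)
  expect_error(itm_loss(m2, list()), "at least one")
})

test_that("ITG loss equals per-token causal cross-entropy, ln V when uniform", {
  m <- tiny_qf()
  emb <- matrix(stats::rnorm(30), 5)
  ids <- c(7L, 12L, 9L)
  # zeroed LM head -> uniform logits -> ln V
  m$params$lm_W$val[] <- 0
  m$params$lm_b$val[] <- 0
  expect_lt(abs(as.numeric(ad_val(itg_loss(m, emb, ids)$loss)) -
                  log(m$config$vocab_size)), 1e-6)
  # hand-computed cross-entropy from the emitted logits
  m2 <- tiny_qf(seed = 8L)
  out <- itg_loss(m2, emb, ids)
  oracle <- mean(vapply(seq_along(out$labels), function(i) {
    z <- out$logits[i, ]
    -log(exp(z[out$labels[i]]) / sum(exp(z)))
  }, numeric(1)))
  expect_equal(as.numeric(ad_val(out$loss)), oracle, tolerance = 1e-8)
  expect_error(itg_loss(m2, emb, integer()), "non-empty")
})

test_that("the total Stage-1 loss is the plain sum across modalities and terms", {
  expect_equal(stage1_total_loss(list(c(1, 1, 1))), 3)
  expect_equal(stage1_total_loss(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))), 18)
  m <- tiny_qf()
  b <- tiny_batch(m, 2L)
  itc <- itc_loss(m, b)
  negs <- mine_hard_negatives(itc$sim)
  itm <- itm_loss(m, itm_pairs(b, negs))
  itg <- itg_loss(m, b$embeddings[[1]], b$texts[[1]])
  total <- stage1_total_loss(list(list(itc$loss, itm$loss, itg$loss)))
  expect_equal(as.numeric(ad_val(total)),
               sum(vapply(list(itc$loss, itm$loss, itg$loss),
                          function(x) as.numeric(ad_val(x)), numeric(1))),
               tolerance = 1e-12)
  expect_error(stage1_total_loss(list()), "at least one")
})

test_that("raw input embeddings receive no gradient and are never updated", {
  m <- tiny_qf()
  emb <- matrix(stats::rnorm(30), 5)
  emb_copy <- emb + 0
  out <- encode_modality(m, emb, graph = TRUE)
  ad_backward(ad_sum(out))
  # every node carrying gradient must be a model parameter
  params <- vq_parameters(m)
  with_grad <- Filter(function(p) !is.null(p$grad), params)
  expect_gt(length(with_grad), 0L)
  expect_identical(emb, emb_copy)
  # graph-walk: no gradient-accumulating leaf outside the parameter set
  param_ids <- vapply(params, function(p) p$id, numeric(1))
  leaves <- new.env()
  walk <- function(node) {
    if (length(node$parents) == 0L && node$requires) {
      leaves[[as.character(node$id)]] <- TRUE
    }
    for (p in node$parents) if (p$requires) walk(p)
  }
  walk(out)
  leaf_ids <- as.numeric(ls(leaves))
  expect_true(all(leaf_ids %in% param_ids))
})

test_that("model configs round-trip losslessly through YAML", {
  cfg <- qformer_config("protein", input_dim = 16L, vocab_size = 64L)
  f <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, f)
  expect_identical(read_config_yaml(f), cfg)
  tc <- train_config(epochs = 5L, seed = 3L)
  write_config_yaml(tc, f)
  expect_identical(read_config_yaml(f), tc)
})
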