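# Generator contracts: shapes, determinism, latent-signal recoverability,
# exact stratum counts, group conservation, and the frozen decoder stand-in.

test_that("generated dataset has the contracted shapes and is seed-deterministic", {
  items <- gen_variant_dataset(4, seed = 7, dims = list(seq_bins = 8L))
  expect_length(items, 4L)
  for (it in items) {
    expect_equal(nrow(it$embeddings$sequence), 16L)  # 2B interleaved
    expect_lte(nrow(it$embeddings$gene), 15L)
    expect_equal(ncol(it$embeddings$gene),
                 attr(items, "dims")$gene_dim + 2L)   # +log-distance, overlap
    expect_equal(nrow(it$embeddings$protein), 2L)     # ref and alt segments
    expect_match(it$record$variant_id, "^[0-9X]+_[0-9]+_[ACGT]_[ACGT]$")
    # caption fields derive from the latent code
    expect_equal(it$caption$fields$consequence, it$record$consequence)
    coding <- it$record$variant_type == "coding"
    expect_equal(it$record$consequence %in%
                   c("missense_variant", "synonymous_variant", "stop_gained"),
                 coding)
  }
  again <- gen_variant_dataset(4, seed = 7, dims = list(seq_bins = 8L))
  expect_identical(items[], again[])
  expect_error(gen_variant_dataset(0), "n must be")
  expect_error(gen_variant_dataset(2, dims = list(seq_dim = -1L)), "positive")
})

test_that("variant type is recoverable from the embeddings by a linear probe", {
  items <- gen_variant_dataset(200, seed = 1)
  # pooled sequence + protein features, logistic probe, 150/50 split
  X <- t(vapply(items, function(it) {
    c(colMeans(it$embeddings$sequence), colMeans(it$embeddings$protein))
  }, numeric(32)))
  y <- vapply(items, function(it) it$record$variant_type == "coding", logical(1))
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X[1:150, ]), y[1:150],
                                         family = stats::binomial()))
  pred <- cbind(1, X[151:200, ]) %*% fit$coefficients > 0
  expect_gt(mean(pred == y[151:200]), 0.9)
})

test_that("target-gene traces hit the requested non-closest fraction exactly", {
  tr <- gen_target_gene_traces(100, frac_non_closest = 0.44, seed = 3)
  expect_equal(sum(vapply(tr, `[[`, logical(1), "non_closest")), 44L)
  # by construction the flag agrees with the closest-gene comparison
  expect_equal(vapply(tr, function(t) t$target_gene != closest_gene_baseline(t),
                      logical(1)),
               vapply(tr, `[[`, logical(1), "non_closest"))
  all_closest <- gen_target_gene_traces(10, frac_non_closest = 0, seed = 1)
  expect_equal(target_gene_accuracy(all_closest)$n_correct, 10L)
  none_closest <- gen_target_gene_traces(10, frac_non_closest = 1, seed = 1)
  expect_equal(target_gene_accuracy(none_closest)$n_correct, 0L)
  expect_error(gen_target_gene_traces(10, frac_non_closest = 1.2), "\\[0, 1\\]")
})

test_that("prioritization groups conserve one causal per group", {
  grps <- gen_prioritization_groups(388, group_size = 10L, seed = 5)
  expect_length(grps, 388L)
  expect_equal(sum(vapply(grps, function(g) nrow(g$candidates), integer(1))),
               3880L)
  for (g in grps[1:20]) {
    expect_equal(sum(g$candidates$variant_id == g$causal_id), 1L)
    expect_length(unique(g$candidates$chromosome), 1L)
  }
  causal_total <- sum(vapply(grps, function(g) {
    sum(g$candidates$variant_id == g$causal_id)
  }, integer(1)))
  expect_equal(causal_total, 388L)
  one <- gen_prioritization_groups(1, group_size = 2L, seed = 1)
  expect_equal(nrow(one[[1]]$candidates), 2L)
  expect_error(gen_prioritization_groups(3, group_size = 1L), ">= 2")
})

test_that("tiny frozen decoder is seed-deterministic with contracted shapes", {
  d1 <- tiny_frozen_decoder(64L, dim = 16L, seed = 0)
  d2 <- tiny_frozen_decoder(64L, dim = 16L, seed = 0)
  expect_identical(d1$params, d2$params)
  expect_true(d1$frozen)
  expect_error(tiny_frozen_decoder(4L), ">= 8")
  prefix <- matrix(stats::rnorm(32 * 16), 32)
  logits <- ad_val(decoder_forward(d1, token_ids = c(5L, 9L, 2L, 7L, 11L),
                                   prefix = prefix))
  expect_equal(dim(logits), c(37L, 64L))
  g1 <- greedy_decode(d1, prefix, c(5L, 9L), max_new_tokens = 6L)
  g2 <- greedy_decode(d1, prefix, c(5L, 9L), max_new_tokens = 6L)
  expect_identical(g1, g2)
  expect_length(g1, 6L)
})
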