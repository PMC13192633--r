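# Field-level caption scoring, closest-gene stratification, and grouped
# prioritization metrics.

toy_caption <- function(chrom = "1", vt = "coding", cons = "missense_variant",
                        genes = c("GA", "GB"), cts = c("neuron")) {
  list(chromosome = chrom, variant_type = vt, consequence = cons,
       nearest_genes = genes, cell_types = cts)
}

test_that("per-field accuracy scores exact matches, set hits and ROUGE", {
  gold <- replicate(10, toy_caption(), simplify = FALSE)
  expect_equal(unname(per_field_accuracy(gold, gold)$accuracy),
               rep(1, 5))
  empty <- replicate(10, list(chromosome = NA, variant_type = NA,
                              consequence = NA, nearest_genes = character(),
                              cell_types = character()), simplify = FALSE)
  expect_equal(unname(per_field_accuracy(empty, gold)$accuracy), rep(0, 5))
  # 7/10 chromosome matches -> 70%
  pred <- gold
  for (i in 1:3) pred[[i]]$chromosome <- "9"
  rep_ <- per_field_accuracy(pred, gold)
  expect_equal(rep_$accuracy[["chromosome"]], 0.7)
  expect_equal(rep_$n, 10L)
  # nearest-genes hit rule: intersection vs strict set equality
  pred2 <- gold
  pred2[[1]]$nearest_genes <- c("GA")
  expect_equal(per_field_accuracy(pred2, gold)$accuracy[["nearest_genes"]], 1)
  expect_equal(per_field_accuracy(pred2, gold, strict = TRUE)$accuracy[["nearest_genes"]],
               0.9)
  # unparseable predicted JSON scores zero but stays in n
  jl <- c(list("{not json"), lapply(gold[-1], caption_json))
  rep3 <- per_field_accuracy(jl, gold)
  expect_equal(rep3$accuracy[["chromosome"]], 0.9)
  expect_equal(rep3$n, 10L)
})

test_that("ROUGE-L F1 matches hand-computed LCS values", {
  expect_equal(rouge_l("neuron hepatocyte", "neuron hepatocyte"), 1)
  expect_equal(rouge_l("", "neuron"), 0)
  # pred {a c}, ref {a b c}: LCS 2, P = 1, R = 2/3, F1 = 0.8
  expect_equal(rouge_l("a c", "a b c"), 0.8)
  expect_equal(rouge_l("c a", "a b c"), 2 * 0.5 * (1 / 3) / (0.5 + 1 / 3))
})

test_that("closest-gene baseline and stratification behave by construction", {
  tr60 <- gen_target_gene_traces(100, frac_non_closest = 0.4, seed = 9)
  expect_equal(target_gene_accuracy(tr60)$accuracy, 0.6)
  strat <- stratify_non_closest(tr60)
  expect_length(strat$non_closest, 40L)
  expect_equal(target_gene_accuracy(strat$non_closest)$accuracy, 0)
  # partition: exhaustive and disjoint
  n_closest <- length(strat$all) - length(strat$non_closest)
  expect_equal(n_closest + length(strat$non_closest), 100L)
  expect_length(stratify_non_closest(
    gen_target_gene_traces(10, 1, seed = 1))$non_closest, 10L)
  expect_length(stratify_non_closest(
    gen_target_gene_traces(10, 0, seed = 1))$non_closest, 0L)
})

test_that("prioritization scoring locates the causal rank with fallbacks", {
  grps <- gen_prioritization_groups(3, group_size = 5L, seed = 2)
  perfect <- lapply(grps, function(g) {
    c(g$causal_id, setdiff(g$candidates$variant_id, g$causal_id))
  })
  res <- score_prioritization(grps, perfect)
  expect_equal(unname(res$top_k), c(1, 1, 1))
  expect_equal(res$mean_rank, 1)
  expect_equal(res$sd_rank, 0)
  # causal at ranks (2, 5, 1): Top-1 = 1/3, mean = 8/3
  ranked <- lapply(seq_along(grps), function(i) {
    ids <- grps[[i]]$candidates$variant_id
    others <- setdiff(ids, grps[[i]]$causal_id)
    switch(i, append(others, grps[[i]]$causal_id, after = 1L),
           c(others, grps[[i]]$causal_id),
           c(grps[[i]]$causal_id, others))
  })
  res <- score_prioritization(grps, ranked)
  expect_equal(res$ranks, c(2, 5, 1))
  expect_equal(res$top_k[["top1"]], 1 / 3)
  expect_equal(res$mean_rank, 8 / 3, tolerance = 1e-12)
  # partial ranking: missing candidates appended in input order
  res2 <- score_prioritization(grps[1], list(grps[[1]]$candidates$variant_id[3]))
  expect_true(res2$ranks >= 1 && res2$ranks <= 5)
  expect_error(score_prioritization(grps[1], list("nonsense_id")),
               "unknown candidate")
})

test_that("random-ranking reference matches enumeration over causal positions", {
  ref <- random_ranking_reference(10)
  expect_equal(unname(ref$top_k), c(0.1, 0.2, 0.3))
  expect_equal(ref$mean_rank, 5.5)
  expect_equal(ref$sd_rank, sqrt(99 / 12))
  expect_equal(random_ranking_reference(1)$top_k[["top1"]], 1)
  expect_equal(random_ranking_reference(2)$mean_rank, 1.5)
  expect_equal(random_ranking_reference(2)$sd_rank, 0.5)
  expect_error(random_ranking_reference(0), ">= 1")
  # exhaustive: causal at every position of a size-4 group
  grp <- gen_prioritization_groups(1, group_size = 4L, seed = 3)[[1]]
  ids <- grp$candidates$variant_id
  others <- setdiff(ids, grp$causal_id)
  rankings <- lapply(1:4, function(p) append(others, grp$causal_id, after = p - 1L))
  res <- score_prioritization(rep(list(grp), 4L), rankings)
  ref4 <- random_ranking_reference(4)
  expect_equal(res$top_k, ref4$top_k)
  expect_equal(res$mean_rank, ref4$mean_rank)
  expect_equal(res$sd_rank, ref4$sd_rank)
  # Top-k monotone nondecreasing
  expect_true(all(diff(res$top_k) >= 0))
})

test_that("ranked lists extract from generated text by first occurrence", {
  cands <- c("1_10_A_G", "1_20_C_T", "1_30_G_A")
  txt <- "most likely 1_30_G_A then 1_10_A_G"
  expect_equal(extract_ranking_from_text(txt, cands),
               c("1_30_G_A", "1_10_A_G", "1_20_C_T"))
})
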