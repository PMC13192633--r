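# Variant-ID parsing, neighborhoods, filters, track selection, interleaving
# and caption serialization.

test_that("variant ids parse and malformed ids raise distinct errors", {
  p <- parse_variant_id("7_117559590_G_A")
  expect_equal(p, list(chromosome = "7", position = 117559590L,
                       ref = "G", alt = "A"))
  expect_equal(parse_variant_id("X_1000_C_T")$chromosome, "X")
  expect_equal(parse_variant_id("chr2_55_A_G")$chromosome, "2")
  expect_error(parse_variant_id("7_117559590_G"), "expected 4 fields")
  expect_error(parse_variant_id("7_abc_G_A"), "not a positive integer")
  expect_error(parse_variant_id("7_5_G_Z"), "alleles")
  expect_equal(format_variant_id("7", 117559590L, "G", "A"), "7_117559590_G_A")
})

test_that("nearest_genes ranks by interval distance with deterministic tie-breaks", {
  ann <- data.frame(chrom = "1",
                    start = c(100L, 500L, 500L, 900L),
                    end = c(200L, 600L, 600L, 1000L),
                    gene_id = c("B", "D", "C", "A"))
  # variant inside gene B
  nb <- nearest_genes("1", 150L, ann)
  expect_true(nb$overlaps[1])
  expect_equal(nb$log_distance[1], 0)
  expect_equal(nb$gene_id[1], "B")
  # equidistant duplicated interval: tie broken lexicographically
  nb <- nearest_genes("1", 550L, ann)
  expect_equal(nb$gene_id[1:2], c("C", "D"))
  # no genes on chromosome
  expect_warning(nb0 <- nearest_genes("5", 10L, ann), "no gene")
  expect_equal(nrow(nb0), 0L)
})

test_that("neighborhood equals brute-force sort and is capped at max_genes", {
  set.seed(42)
  for (trial in 1:5) {
    n_genes <- 20L
    start <- sort(sample.int(1e6, n_genes))
    ann <- data.frame(chrom = "3", start = start,
                      end = start + sample(100:5000, n_genes),
                      gene_id = sprintf("g%02d", sample.int(99, n_genes)))
    pos <- sample.int(1e6, 1L)
    nb <- nearest_genes("3", pos, ann)
    expect_equal(nrow(nb), 15L)
    # oracle: exhaustive distance computation + sort
    p0 <- pos - 1L
    d <- pmax(ann$start - p0, p0 - (ann$end - 1L), 0L)
    oracle <- ann$gene_id[order(d, ann$start, ann$gene_id)][1:15]
    expect_equal(nb$gene_id, oracle)
    expect_true(!is.unsorted(nb$distance))
  }
  # fewer genes than the cap: no padding rows
  nb <- nearest_genes("3", 100L, data.frame(
    chrom = "3", start = c(1L, 50L, 900L), end = c(10L, 60L, 950L),
    gene_id = c("a", "b", "c")))
  expect_equal(nrow(nb), 3L)
})

test_that("genome-build match filter keeps exactly the agreement set", {
  expect_true(build_match_filter("BRCA1", "BRCA1")$keep)
  expect_false(build_match_filter("BRCA1", "BRCA2")$keep)
  expect_equal(build_match_filter("BRCA1", NA)$reason, "missing_id")
  expect_true(build_match_filter(" brca1 ", "BRCA1")$keep)
  # counting oracle: 7.3% injected disagreements -> 92.7% survive
  n <- 1000L
  labeled <- sprintf("G%03d", seq_len(n))
  located <- labeled
  bad <- seq_len(73L) * 13L %% n + 1L
  bad <- unique(bad)[1:73]
  located[bad] <- "OTHER"
  kept <- vapply(seq_len(n), function(i) {
    build_match_filter(located[i], labeled[i])$keep
  }, logical(1))
  expect_equal(mean(kept), 0.927)
})

test_that("top_tracks ranks by absolute effect size with id tie-breaks", {
  sc <- data.frame(track_id = letters[1:6], cell_type = "x",
                   effect_size = c(5, -7, 1, -2, 3, 0))
  expect_equal(top_tracks(sc, 5L)$track_id, c("b", "a", "e", "d", "c"))
  expect_equal(nrow(top_tracks(sc[1:3, ], 5L)), 3L)
  set.seed(7)
  sc <- data.frame(track_id = sprintf("t%03d", 1:100), cell_type = "y",
                   effect_size = stats::rnorm(100))
  got <- top_tracks(sc, 100L)$track_id
  oracle <- sc$track_id[order(-abs(sc$effect_size), sc$track_id)]
  expect_equal(got, oracle)
})

test_that("ref/alt interleaving doubles the bin count and inverts exactly", {
  ref <- matrix(stats::rnorm(256 * 4), 256)
  alt <- matrix(stats::rnorm(256 * 4), 256)
  x <- interleave_ref_alt(ref, alt)
  expect_equal(nrow(x), 512L)
  expect_equal(x[1, ], ref[1, ])
  expect_equal(x[2, ], alt[1, ])
  back <- deinterleave_ref_alt(x)
  expect_identical(back$ref, ref)
  expect_identical(back$alt, alt)
  one <- interleave_ref_alt(ref[1, , drop = FALSE], alt[1, , drop = FALSE])
  expect_equal(one, rbind(ref[1, ], alt[1, ]))
  expect_error(interleave_ref_alt(ref, alt[1:10, ]), "shapes differ")
})

test_that("captions serialize deterministically and round trip", {
  rec <- list(chromosome = "7", variant_type = "noncoding",
              consequence = "intron_variant",
              nearest_genes = c("CFTR", "ASZ1"),
              cell_types = c("lung_epithelium"))
  cp <- build_caption(rec)
  expect_identical(names(cp$fields),
                   c("chromosome", "variant_type", "consequence",
                     "nearest_genes", "cell_types"))
  back <- parse_caption(cp$json)
  expect_equal(back, cp$fields)
  expect_identical(cp$json, build_caption(rec)$json)
  # missing cell types -> empty list field present
  rec2 <- rec; rec2$cell_types <- NULL
  cp2 <- build_caption(rec2)
  expect_true(grepl("\"cell_types\":\\[\\]", cp2$json))
  # missing consequence -> explicit null with warning
  rec3 <- rec; rec3$consequence <- NULL
  expect_warning(cp3 <- build_caption(rec3), "consequence")
  expect_true(grepl("\"consequence\":null", cp3$json))
})
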