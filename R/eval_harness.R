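# Evaluation surfaces: per-field caption accuracy, target-gene
# identification with closest-gene stratification, and grouped variant
# prioritization (Top-k accuracy / mean rank).

.norm_label <- function(x) tolower(trimws(as.character(x)))

#' ROUGE-L F1 between two strings
#'
#' Longest-common-subsequence precision/recall over tokens
#' (see [vq_tokenize()]), combined as the balanced F-score.
#'
#' @param pred,ref character scalars.
#' @export
rouge_l <- function(pred, ref) {
  a <- vq_tokenize(pred); b <- vq_tokenize(ref)
  if (length(a) == 0L || length(b) == 0L) return(0)
  dp <- matrix(0L, length(a) + 1L, length(b) + 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      dp[i + 1L, j + 1L] <- if (a[i] == b[j]) dp[i, j] + 1L
                            else max(dp[i, j + 1L], dp[i + 1L, j])
    }
  }
  lcs <- dp[length(a) + 1L, length(b) + 1L]
  if (lcs == 0L) return(0)
  p <- lcs / length(a); r <- lcs / length(b)
  2 * p * r / (p + r)
}

#' Per-field caption accuracy report
#'
#' Chromosome, variant type and consequence are scored by normalized exact
#' match; nearest genes as a hit when the predicted and gold gene sets
#' intersect (`strict = TRUE` demands set equality); cell types as mean
#' ROUGE-L F1. Unparseable predictions score 0 on every field but stay in
#' the denominator.
#'
#' @param predicted,gold equal-length lists of caption field lists (see
#'   [parse_caption()]) or JSON strings.
#' @param strict require exact set match for nearest genes.
#' @return `field_report`: list with `accuracy` (named numeric, 5 fields)
#'   and `n`.
#' @export
per_field_accuracy <- function(predicted, gold, strict = FALSE) {
  stopifnot(length(predicted) == length(gold), length(gold) > 0L)
  as_fields <- function(x) {
    if (is.character(x)) parse_caption(x)
    else if (inherits(x, "caption_doc")) x$fields
    else x
  }
  fields <- c("chromosome", "variant_type", "consequence",
              "nearest_genes", "cell_types")
  acc <- stats::setNames(numeric(5L), fields)
  n <- length(gold)
  for (i in seq_len(n)) {
    g <- as_fields(gold[[i]])
    p <- as_fields(predicted[[i]])
    if (is.null(p)) next  # unparseable: zero on all fields
    for (f in c("chromosome", "variant_type", "consequence")) {
      if (length(p[[f]]) == 1L && !is.na(p[[f]]) &&
          .norm_label(p[[f]]) == .norm_label(g[[f]])) {
        acc[f] <- acc[f] + 1
      }
    }
    pg <- .norm_label(p$nearest_genes); gg <- .norm_label(g$nearest_genes)
    hit <- if (strict) setequal(pg, gg) && length(pg) > 0L
           else length(intersect(pg, gg)) > 0L
    if (hit) acc["nearest_genes"] <- acc["nearest_genes"] + 1
    acc["cell_types"] <- acc["cell_types"] +
      rouge_l(paste(p$cell_types, collapse = " "),
              paste(g$cell_types, collapse = " "))
  }
  structure(list(accuracy = acc / n, n = n), class = "field_report")
}

#' Closest-gene baseline prediction
#'
#' Predicts the target gene of a trace as the neighborhood gene at minimal
#' distance (the neighborhood is already distance-sorted with deterministic
#' tie-breaks).
#'
#' @param trace a trace from [gen_target_gene_traces()] (needs
#'   `neighborhood`).
#' @return gene id, or `NA_character_` for an empty neighborhood (scored
#'   incorrect downstream).
#' @export
closest_gene_baseline <- function(trace) {
  nb <- trace$neighborhood
  if (is.null(nb) || nrow(nb) == 0L) return(NA_character_)
  nb$gene_id[1L]
}

#' Accuracy of a target-gene predictor over traces
#' @param traces list of traces.
#' @param predict_fn function(trace) -> gene id; defaults to the
#'   closest-gene baseline.
#' @return list: `accuracy`, `n_correct`, `n`.
#' @export
target_gene_accuracy <- function(traces, predict_fn = closest_gene_baseline) {
  preds <- vapply(traces, predict_fn, character(1))
  gold <- vapply(traces, function(tr) tr$target_gene, character(1))
  ok <- !is.na(preds) & .norm_label(preds) == .norm_label(gold)
  list(accuracy = mean(ok), n_correct = sum(ok), n = length(traces))
}

#' Stratify traces by whether the target is the closest gene
#'
#' @param traces list of traces.
#' @return list: `all` (every trace) and `non_closest` (the subset whose
#'   target differs from the closest gene); the two strata partition `all`.
#' @export
stratify_non_closest <- function(traces) {
  is_nc <- vapply(traces, function(tr) {
    !identical(closest_gene_baseline(tr), tr$target_gene)
  }, logical(1))
  list(all = traces, non_closest = traces[is_nc])
}

#' Score grouped variant prioritization
#'
#' The causal variant's 1-based rank is located in each group's ranked
#' candidate list; candidates missing from a ranking are appended in input
#' order (documented fallback). Reports Top-k accuracy for k = 1..3, the
#' mean rank and the population standard deviation of ranks.
#'
#' @param groups list from [gen_prioritization_groups()].
#' @param rankings list (same length) of character vectors of variant ids,
#'   most-likely-causal first.
#' @return `prioritization_result`: list with `ranks`, `top_k` (k = 1..3),
#'   `mean_rank`, `sd_rank`, `n_groups`.
#' @export
score_prioritization <- function(groups, rankings) {
  stopifnot(length(groups) == length(rankings))
  ranks <- vapply(seq_along(groups), function(gi) {
    grp <- groups[[gi]]
    cand <- grp$candidates$variant_id
    rk <- as.character(rankings[[gi]])
    unknown <- setdiff(rk, cand)
    if (length(unknown) > 0L) {
      stop(sprintf("group %s: ranking references unknown candidate(s): %s",
                   grp$group_id, paste(unknown, collapse = ", ")))
    }
    rk <- c(rk, setdiff(cand, rk))  # append unranked in input order
    match(grp$causal_id, rk)
  }, numeric(1))
  top_k <- vapply(1:3, function(k) mean(ranks <= k), numeric(1))
  names(top_k) <- paste0("top", 1:3)
  mu <- mean(ranks)
  structure(list(ranks = ranks, top_k = top_k, mean_rank = mu,
                 sd_rank = sqrt(mean((ranks - mu)^2)),
                 n_groups = length(groups)),
            class = "prioritization_result")
}

#' Analytic reference for uniform random rankings
#'
#' Under a uniformly random ranking of a group of size n, the causal rank is
#' uniform on 1..n: Top-k = k/n, mean rank (n+1)/2, population standard
#' deviation sqrt((n^2 - 1)/12).
#'
#' @param group_size group size n (>= 1).
#' @return list: `top_k` (k = 1..3, capped at 1), `mean_rank`, `sd_rank`.
#' @export
random_ranking_reference <- function(group_size) {
  if (group_size < 1L) stop("group_size must be >= 1")
  n <- group_size
  top_k <- pmin(1:3 / n, 1)
  names(top_k) <- paste0("top", 1:3)
  list(top_k = top_k, mean_rank = (n + 1) / 2,
       sd_rank = sqrt((n^2 - 1) / 12))
}

#' Extract a ranked candidate list from generated text
#'
#' Candidates are ranked by first occurrence of their variant id in the
#' text; unmentioned candidates are appended in input order.
#'
#' @param text character scalar (model output).
#' @param candidates character vector of candidate variant ids.
#' @export
extract_ranking_from_text <- function(text, candidates) {
  pos <- vapply(candidates, function(id) {
    hit <- regexpr(id, text, fixed = TRUE)[1]
    if (hit < 0) Inf else as.numeric(hit)
  }, numeric(1))
  mentioned <- candidates[is.finite(pos)]
  c(mentioned[order(pos[is.finite(pos)])], candidates[!is.finite(pos)])
}
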