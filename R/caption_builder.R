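# Variant caption construction: variant-ID parsing, nearest-gene
# neighborhoods against a gene annotation, dataset filters, track selection,
# ref/alt interleaving and deterministic JSON serialization.
#
# Coordinate conventions: variant positions are 1-based (as in the
# chrom_pos_ref_alt identifier convention); gene intervals are half-open
# 0-based (BED convention). All conversions happen inside `nearest_genes`.

.valid_alleles <- c("A", "C", "G", "T")

#' Parse a chrom_pos_ref_alt variant identifier
#'
#' @param id underscore-separated string: chromosome, 1-based position,
#'   reference allele, alternate allele. A leading "chr" on the chromosome is
#'   stripped.
#' @return list with `chromosome`, `position` (integer), `ref`, `alt`.
#' @examples
#' parse_variant_id("7_117559590_G_A")
#' @export
parse_variant_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  parts <- strsplit(id, "_", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop(sprintf("variant id '%s': expected 4 fields, got %d", id, length(parts)))
  }
  chrom <- sub("^chr", "", parts[1])
  pos <- suppressWarnings(as.integer(parts[2]))
  if (is.na(pos) || pos <= 0L) {
    stop(sprintf("variant id '%s': position '%s' is not a positive integer",
                 id, parts[2]))
  }
  ref <- toupper(parts[3]); alt <- toupper(parts[4])
  if (!ref %in% .valid_alleles || !alt %in% .valid_alleles) {
    stop(sprintf("variant id '%s': alleles must be one of A/C/G/T", id))
  }
  list(chromosome = chrom, position = pos, ref = ref, alt = alt)
}

#' Render a variant identifier from its components
#' @param chromosome,position,ref,alt variant fields (position 1-based).
#' @export
format_variant_id <- function(chromosome, position, ref, alt) {
  paste(sub("^chr", "", chromosome), position, ref, alt, sep = "_")
}

# distance in bp from a 1-based position to a half-open 0-based interval
# [start0, end0); 0 when the position falls inside.
.interval_distance <- function(pos, start0, end0) {
  p0 <- pos - 1L  # 0-based coordinate of the base
  pmax(start0 - p0, p0 - (end0 - 1L), 0L)
}

#' Nearest protein-coding genes of a variant
#'
#' Ranks the annotation's genes on the variant's chromosome by minimal
#' distance to the gene interval (0 inside the gene body), breaking ties by
#' ascending interval start and then lexicographic gene id, and returns at
#' most `max_genes` of them with the two derived feature columns used by the
#' gene modality: `log_distance = log1p(distance)` and an `overlaps` flag.
#'
#' @param chromosome,position variant location (position 1-based).
#' @param annotation a [synthetic_genome()] or a data frame with columns
#'   `chrom`, `start`, `end` (half-open 0-based), `gene_id`.
#' @param max_genes neighborhood cap (default 15).
#' @return data frame with columns gene_id, distance, log_distance, overlaps,
#'   sorted by ascending distance; zero rows (with a warning) when the
#'   chromosome has no annotated gene.
#' @export
nearest_genes <- function(chromosome, position, annotation, max_genes = 15L) {
  genes <- if (inherits(annotation, "synthetic_genome")) annotation$genes else annotation
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  chromosome <- sub("^chr", "", chromosome)
  g <- genes[sub("^chr", "", genes$chrom) == chromosome, , drop = FALSE]
  if (nrow(g) == 0L) {
    warning(sprintf("no gene annotated on chromosome %s", chromosome))
    return(data.frame(gene_id = character(), distance = integer(),
                      log_distance = numeric(), overlaps = logical()))
  }
  d <- .interval_distance(position, g$start, g$end)
  ord <- order(d, g$start, g$gene_id, method = "radix")
  g <- g[ord, , drop = FALSE]; d <- d[ord]
  keep <- seq_len(min(max_genes, nrow(g)))
  data.frame(gene_id = g$gene_id[keep],
             distance = as.integer(d[keep]),
             log_distance = log1p(d[keep]),
             overlaps = d[keep] == 0L,
             row.names = NULL)
}

#' Genome-build agreement filter
#'
#' Keeps a variant only when the closest gene found by coordinate lookup
#' agrees with the closest gene recorded in the source labels; disagreement
#' (or a missing id) drops the variant with a reason code.
#'
#' @param locator_closest gene id from coordinate lookup.
#' @param labeled_closest gene id from the label source.
#' @return list with `keep` (logical) and `reason` ("ok", "mismatch",
#'   "missing_id").
#' @export
build_match_filter <- function(locator_closest, labeled_closest) {
  norm <- function(x) toupper(trimws(as.character(x)))
  if (is.null(locator_closest) || is.null(labeled_closest) ||
      is.na(locator_closest) || is.na(labeled_closest) ||
      !nzchar(norm(locator_closest)) || !nzchar(norm(labeled_closest))) {
    return(list(keep = FALSE, reason = "missing_id"))
  }
  same <- norm(locator_closest) == norm(labeled_closest)
  list(keep = same, reason = if (same) "ok" else "mismatch")
}

#' Top tracks by absolute effect size
#'
#' @param scores data frame with columns `track_id`, `cell_type`,
#'   `effect_size`.
#' @param k number of tracks to keep (default 5).
#' @return the `k` rows with the largest `|effect_size|`, descending, ties
#'   broken by track id.
#' @export
top_tracks <- function(scores, k = 5L) {
  stopifnot(all(c("track_id", "cell_type", "effect_size") %in% names(scores)),
            all(is.finite(scores$effect_size)))
  ord <- order(-abs(scores$effect_size), scores$track_id, method = "radix")
  out <- scores[ord, , drop = FALSE]
  out[seq_len(min(k, nrow(out))), , drop = FALSE]
}

#' Interleave reference and alternate sequence bins
#'
#' Builds the 2B-row sequence-modality input: row 2i-1 is ref bin i, row 2i
#' is alt bin i.
#'
#' @param ref_bins,alt_bins B x d matrices.
#' @export
interleave_ref_alt <- function(ref_bins, alt_bins) {
  stopifnot(is.matrix(ref_bins), is.matrix(alt_bins))
  if (!all(dim(ref_bins) == dim(alt_bins))) {
    stop(sprintf("ref/alt bin shapes differ: %dx%d vs %dx%d",
                 nrow(ref_bins), ncol(ref_bins), nrow(alt_bins), ncol(alt_bins)))
  }
  B <- nrow(ref_bins)
  out <- matrix(0, 2L * B, ncol(ref_bins))
  out[seq(1L, 2L * B, by = 2L), ] <- ref_bins
  out[seq(2L, 2L * B, by = 2L), ] <- alt_bins
  out
}

#' Undo [interleave_ref_alt()]
#' @param x a 2B x d interleaved matrix.
#' @return list with `ref` and `alt` (B x d each).
#' @export
deinterleave_ref_alt <- function(x) {
  stopifnot(is.matrix(x), nrow(x) %% 2L == 0L)
  list(ref = x[seq(1L, nrow(x), by = 2L), , drop = FALSE],
       alt = x[seq(2L, nrow(x), by = 2L), , drop = FALSE])
}

#' Build the structured JSON caption of a variant
#'
#' The caption carries exactly five fields in fixed order: chromosome,
#' variant_type, consequence, nearest_genes, cell_types. Serialization is
#' deterministic (byte-identical across runs for equal records).
#'
#' @param record a list with fields `chromosome`, `variant_type`,
#'   `consequence`, `nearest_genes` (character vector), `cell_types`
#'   (character vector). A missing/NA consequence is serialized as an
#'   explicit null, with a warning.
#' @return object of class `caption_doc`: list with `fields` (the parsed
#'   caption) and `json` (its canonical serialization).
#' @export
build_caption <- function(record) {
  consequence <- record$consequence
  if (is.null(consequence) || length(consequence) == 0L || is.na(consequence)) {
    warning("record has no consequence; caption carries an explicit null")
    consequence <- NA_character_
  }
  fields <- list(
    chromosome = as.character(record$chromosome),
    variant_type = as.character(record$variant_type),
    consequence = consequence,
    nearest_genes = as.character(record$nearest_genes %||% character()),
    cell_types = as.character(record$cell_types %||% character())
  )
  structure(list(fields = fields, json = caption_json(fields)),
            class = "caption_doc")
}

#' @rdname build_caption
#' @param fields caption field list.
#' @export
caption_json <- function(fields) {
  as.character(jsonlite::toJSON(
    list(chromosome = jsonlite::unbox(fields$chromosome),
         variant_type = jsonlite::unbox(fields$variant_type),
         consequence = if (is.na(fields$consequence)) NULL
                       else jsonlite::unbox(fields$consequence),
         nearest_genes = fields$nearest_genes,
         cell_types = fields$cell_types),
    null = "null", auto_unbox = FALSE))
}

#' @rdname build_caption
#' @param json caption JSON string.
#' @export
parse_caption <- function(json) {
  out <- tryCatch(jsonlite::fromJSON(json, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(out)) return(NULL)
  list(chromosome = as.character(out$chromosome %||% NA_character_),
       variant_type = as.character(out$variant_type %||% NA_character_),
       consequence = as.character(out$consequence %||% NA_character_),
       nearest_genes = as.character(out$nearest_genes %||% character()),
       cell_types = as.character(out$cell_types %||% character()))
}

#' Caption text used by the text side of the aligners
#'
#' Flattens a caption to the token stream consumed by the caption encoder:
#' field names and values, punctuation dropped.
#'
#' @param caption a `caption_doc` or caption field list.
#' @export
caption_text <- function(caption) {
  f <- if (inherits(caption, "caption_doc")) caption$fields else caption
  paste(c("chromosome", f$chromosome,
          "variant_type", f$variant_type,
          "consequence", if (is.na(f$consequence)) "null" else f$consequence,
          "nearest_genes", f$nearest_genes,
          "cell_types", f$cell_types), collapse = " ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
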