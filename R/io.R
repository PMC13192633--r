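# External interfaces: JSON Lines caption records, BED gene intervals,
# binary tensor export with a JSON sidecar manifest, YAML config round
# trips, and single-file model checkpoints.

#' Read / write JSON Lines records
#'
#' @param records list of serializable records.
#' @param path file path.
#' @export
write_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(as.character(jsonlite::toJSON(r, auto_unbox = TRUE,
                                             null = "null", digits = NA)), con)
  }
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Write caption documents as JSON Lines
#' @param captions list of `caption_doc` objects.
#' @param path file path.
#' @export
write_captions_jsonl <- function(captions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cp in captions) writeLines(cp$json, con)
  invisible(path)
}

#' Write / read gene intervals as BED
#'
#' Plain BED6: half-open 0-based intervals, score column 0. The internal
#' gene table already uses BED coordinates, so this is a column mapping.
#'
#' @param genome a [synthetic_genome()] or its `genes` data frame.
#' @param path file path.
#' @export
write_genes_bed <- function(genome, path) {
  genes <- if (inherits(genome, "synthetic_genome")) genome$genes else genome
  bed <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                    name = genes$gene_id, score = 0L,
                    strand = genes$strand %||% "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed)[1:4] <- c("chrom", "start", "end", "gene_id")
  if (ncol(bed) >= 6L) names(bed)[6] <- "strand"
  bed$chrom <- as.character(bed$chrom)
  bed[, intersect(c("chrom", "start", "end", "gene_id", "strand"), names(bed))]
}

#' Read variants from a VCF file or a variant-ID list
#'
#' VCF parsing goes through the vcfR package; a plain text file with one
#' chrom_pos_ref_alt id per line (or a character vector of ids) is also
#' accepted.
#'
#' @param x path to a VCF / id-list file, or a character vector of ids.
#' @return data frame with chromosome, position, ref, alt, variant_id.
#' @export
read_variants <- function(x) {
  ids <- if (length(x) == 1L && file.exists(x)) {
    if (grepl("\\.vcf(\\.gz)?$", x)) {
      if (!requireNamespace("vcfR", quietly = TRUE)) {
        stop("reading VCF requires the vcfR package")
      }
      v <- vcfR::read.vcfR(x, verbose = FALSE)
      fx <- vcfR::getFIX(v)
      apply(fx, 1L, function(r) {
        format_variant_id(r[["CHROM"]], as.integer(r[["POS"]]),
                          r[["REF"]], r[["ALT"]])
      })
    } else readLines(x)
  } else as.character(x)
  ids <- ids[nzchar(trimws(ids))]
  parsed <- lapply(ids, parse_variant_id)
  data.frame(
    chromosome = vapply(parsed, `[[`, character(1), "chromosome"),
    position = vapply(parsed, `[[`, integer(1), "position"),
    ref = vapply(parsed, `[[`, character(1), "ref"),
    alt = vapply(parsed, `[[`, character(1), "alt"),
    variant_id = vapply(parsed, function(p) {
      format_variant_id(p$chromosome, p$position, p$ref, p$alt)
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Export embeddings as binary tensors with a sidecar manifest
#'
#' Each matrix is written as little-endian doubles (row-major) next to a
#' JSON manifest listing modality, shape and dtype.
#'
#' @param embeddings named list of numeric matrices.
#' @param dir output directory (created if missing).
#' @export
write_embeddings <- function(embeddings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(names(embeddings), function(nm) {
    m <- embeddings[[nm]]
    f <- file.path(dir, paste0(nm, ".bin"))
    con <- file(f, "wb")
    writeBin(as.numeric(t(m)), con, size = 8L, endian = "little")
    close(con)
    list(modality = nm, file = basename(f),
         shape = dim(m), dtype = "float64")
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  out <- list()
  for (entry in manifest) {
    shape <- unlist(entry$shape)
    con <- file(file.path(dir, entry$file), "rb")
    v <- readBin(con, "numeric", n = prod(shape), size = 8L, endian = "little")
    close(con)
    out[[entry$modality]] <- matrix(v, shape[1], shape[2], byrow = TRUE)
  }
  out
}

#' Round-trip a model configuration through YAML
#'
#' @param config a `qformer_config`, `master_config` or `train_config`.
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  obj <- unclass(config)
  obj$.class <- class(config)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  ints <- vapply(obj, function(x) is.numeric(x) && length(x) == 1L &&
                   !is.na(x) && x == round(x) && abs(x) < .Machine$integer.max,
                 logical(1))
  nonint <- c("lr", "weight_decay", "warmup_frac", "clip_norm")
  for (nm in names(obj)[ints]) {
    if (!nm %in% nonint) obj[[nm]] <- as.integer(obj[[nm]])
  }
  structure(obj, class = cls)
}

#' Load instruction templates from a YAML prompt file
#'
#' @param path YAML file; defaults to the templates shipped with the
#'   package.
#' @return named character vector of per-field instruction strings.
#' @export
load_instruction_templates <- function(path = system.file("prompts", "instructions.yaml",
                                                          package = "varqform")) {
  y <- yaml::read_yaml(path)
  unlist(y$fields)
}

#' Apply the genome-build match filter over a variant table
#'
#' Runs [build_match_filter()] on every row and (optionally) writes the
#' per-variant ledger as TSV with reason codes.
#'
#' @param variants data frame with columns `variant_id`, `locator_closest`,
#'   `labeled_closest`.
#' @param ledger_path optional TSV path for the filter ledger.
#' @return the input with logical `keep` and character `reason` columns.
#' @export
filter_variants <- function(variants, ledger_path = NULL) {
  res <- lapply(seq_len(nrow(variants)), function(i) {
    build_match_filter(variants$locator_closest[i], variants$labeled_closest[i])
  })
  variants$keep <- vapply(res, `[[`, logical(1), "keep")
  variants$reason <- vapply(res, `[[`, character(1), "reason")
  if (!is.null(ledger_path)) {
    utils::write.table(variants, ledger_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  variants
}

#' Write evaluation reports as TSV
#'
#' @param report a `field_report` from [per_field_accuracy()] or a
#'   `prioritization_result` from [score_prioritization()].
#' @param path output TSV path.
#' @export
write_report_tsv <- function(report, path) {
  df <- if (inherits(report, "field_report")) {
    data.frame(field = names(report$accuracy),
               accuracy_pct = round(100 * unname(report$accuracy), 2),
               n = report$n)
  } else if (inherits(report, "prioritization_result")) {
    data.frame(top1_pct = round(100 * report$top_k[["top1"]], 2),
               top2_pct = round(100 * report$top_k[["top2"]], 2),
               top3_pct = round(100 * report$top_k[["top3"]], 2),
               mean_rank = round(report$mean_rank, 2),
               sd_rank = round(report$sd_rank, 2),
               n_groups = report$n_groups)
  } else stop("unsupported report type")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# flatten an ad parameter tree into named numeric vectors
.flatten_weights <- function(node, prefix = "") {
  if (ad_is(node)) {
    out <- list()
    out[[prefix]] <- node
    return(out)
  }
  if (!is.list(node)) return(list())
  out <- list()
  nms <- names(node) %||% as.character(seq_along(node))
  for (i in seq_along(node)) {
    nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
    out <- c(out, .flatten_weights(node[[i]], paste0(prefix, if (nzchar(prefix)) "/" else "", nm)))
  }
  out
}

#' Save / load a model checkpoint
#'
#' Single-file archive (tar) holding the config as JSON plus one binary
#' blob per weight matrix and a shape manifest.
#'
#' @param model a `qformer` or `master_qformer`.
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  tmp <- tempfile("ckpt")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  jsonlite::write_json(c(unclass(model$config), list(.class = class(model)[1])),
                       file.path(tmp, "config.json"), auto_unbox = TRUE)
  flat <- .flatten_weights(model$params)
  con <- file(file.path(tmp, "weights.bin"), "wb")
  for (w in flat) writeBin(as.numeric(t(w$val)), con, size = 8L, endian = "little")
  close(con)
  manifest <- lapply(names(flat), function(nm) {
    list(name = nm, shape = dim(flat[[nm]]$val))
  })
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE)
  abs_path <- file.path(normalizePath(dirname(path)), basename(path))
  owd <- setwd(tmp)
  on.exit(setwd(owd), add = TRUE, after = FALSE)
  utils::tar(abs_path, files = c("config.json", "manifest.json", "weights.bin"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @param model_into an initialized model of matching architecture whose
#'   weights are overwritten in place.
#' @export
load_checkpoint <- function(path, model_into) {
  tmp <- tempfile("ckpt")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::untar(path, exdir = tmp)
  manifest <- jsonlite::fromJSON(file.path(tmp, "manifest.json"),
                                 simplifyVector = FALSE)
  flat <- .flatten_weights(model_into$params)
  con <- file(file.path(tmp, "weights.bin"), "rb")
  on.exit(close(con), add = TRUE, after = FALSE)
  for (entry in manifest) {
    shape <- unlist(entry$shape)
    v <- readBin(con, "numeric", n = prod(shape), size = 8L, endian = "little")
    target <- flat[[entry$name]]
    if (is.null(target)) stop("checkpoint weight not in model: ", entry$name)
    target$val <- matrix(v, shape[1], shape[2], byrow = TRUE)
  }
  model_into
}
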