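# Two-stage optimization regime.
#
# Stage 1 jointly trains the modality Q-formers on the summed ITC + ITM +
# ITG losses; Stage 2 trains the master fusion model (and keeps refining the
# Stage-1 models and the output projection) with next-token prediction
# against a frozen decoder. AdamW, cosine schedule with linear warmup over
# 10% of steps, and global gradient clipping at norm 1.0 follow the
# published recipe; desk-scale architectural defaults (width 32, 2 layers)
# keep a full two-stage run within minutes on one CPU.

#' Training configuration
#'
#' @param lr peak learning rate (default 1e-4).
#' @param weight_decay AdamW decoupled weight decay (default 0.05).
#' @param warmup_frac linear-warmup fraction of total steps, in (0, 1).
#' @param clip_norm global gradient-clipping norm (> 0).
#' @param epochs training epochs (published default 15; desk-scale runs use
#'   fewer).
#' @param batch_size items per step.
#' @param mixed_precision reserved flag; off (full precision) for bitwise
#'   reproducibility on CPU.
#' @param seed run seed (controls shuffling, mining and initialization).
#' @export
train_config <- function(lr = 1e-4, weight_decay = 0.05, warmup_frac = 0.1,
                         clip_norm = 1.0, epochs = 15L, batch_size = 16L,
                         mixed_precision = FALSE, seed = 0L) {
  if (warmup_frac <= 0 || warmup_frac >= 1) stop("warmup_frac must be in (0, 1)")
  if (clip_norm <= 0) stop("clip_norm must be > 0")
  structure(list(lr = lr, weight_decay = weight_decay,
                 warmup_frac = warmup_frac, clip_norm = clip_norm,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 mixed_precision = isTRUE(mixed_precision),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine learning-rate schedule with linear warmup
#'
#' @param step 0-based step index.
#' @param total_steps total steps in the run.
#' @param config a [train_config()].
#' @return learning rate at `step`: 0 at step 0, `config$lr` at the end of
#'   warmup, cosine decay to 0 afterwards.
#' @export
lr_schedule <- function(step, total_steps, config) {
  W <- max(1L, round(config$warmup_frac * total_steps))
  ifelse(step < W, config$lr * step / W,
         config$lr * 0.5 * (1 + cos(pi * (step - W) / max(1L, total_steps - W))))
}

.adamw_init <- function(params) {
  lapply(params, function(p) list(m = p$val * 0, v = p$val * 0, t = 0L))
}

.adamw_step <- function(params, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) g <- p$val * 0
    s <- state[[i]]
    s$t <- s$t + 1L
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^s$t)
    vhat <- s$v / (1 - beta2^s$t)
    p$val <- p$val - lr * (mhat / (sqrt(vhat) + eps) + wd * p$val)
    state[[i]] <- s
  }
  state
}

#' Clip gradients to a global norm
#'
#' @param params list of `ad` parameters with accumulated gradients.
#' @param max_norm clipping threshold.
#' @return the pre-clip global norm (invisibly scales gradients in place
#'   when it exceeds `max_norm`).
#' @export
clip_global_norm <- function(params, max_norm) {
  sq <- sum(vapply(params, function(p) {
    if (is.null(p$grad)) 0 else sum(p$grad^2)
  }, numeric(1)))
  nrm <- sqrt(sq)
  if (nrm > max_norm) {
    sc <- max_norm / nrm
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
  }
  nrm
}

#' Build desk-scale Stage-1 models for a generated dataset
#'
#' @param items output of [gen_variant_dataset()].
#' @param modalities subset of c("sequence", "gene", "protein").
#' @param vocab caption vocabulary (built from `items` when NULL).
#' @param hidden_dim,num_layers,num_heads,num_queries desk-scale
#'   architecture knobs; `num_queries = NULL` keeps the per-modality
#'   defaults (32/8/8).
#' @param seed initialization seed.
#' @return list: `models` (named list of `qformer`), `vocab`.
#' @export
build_stage1_models <- function(items, modalities = c("sequence", "gene", "protein"),
                                vocab = NULL, hidden_dim = 32L, num_layers = 2L,
                                num_heads = 4L, num_queries = NULL, seed = 0L) {
  if (is.null(vocab)) vocab <- dataset_vocab(items)
  input_dims <- attr(items, "input_dims")
  models <- stats::setNames(lapply(seq_along(modalities), function(i) {
    m <- modalities[i]
    cfg <- qformer_config(m, input_dim = input_dims[[m]],
                          vocab_size = length(vocab),
                          num_layers = num_layers, hidden_dim = hidden_dim,
                          num_heads = num_heads, num_queries = num_queries,
                          contrast_dim = hidden_dim)
    qformer_init(cfg, seed = seed + i)
  }), modalities)
  list(models = models, vocab = vocab)
}

.stage1_batch <- function(items, idx, vocab, modality) {
  list(embeddings = lapply(items[idx], function(it) it$embeddings[[modality]]),
       texts = lapply(items[idx], function(it) {
         vq_encode(vocab, caption_text(it$caption))
       }))
}

#' Stage-1 training: joint alignment of the modality Q-formers
#'
#' Optimizes the plain sum of the per-modality ITC + ITM + ITG losses with
#' AdamW under the cosine/warmup schedule, recording every term per step.
#'
#' @param items output of [gen_variant_dataset()] (embedding-caption pairs).
#' @param config a [train_config()].
#' @param models named list of `qformer` models (built at desk scale from
#'   the data when NULL).
#' @param modalities modalities to train.
#' @param vocab caption vocabulary.
#' @return list: `models`, `vocab`, `history` (one row per step with loss
#'   terms, learning rate and in-batch retrieval per modality), `config`.
#' @export
train_stage1 <- function(items, config, models = NULL,
                         modalities = c("sequence", "gene", "protein"),
                         vocab = NULL) {
  if (length(items) < 1L) stop("empty dataset")
  if (is.null(models)) {
    built <- build_stage1_models(items, modalities, vocab, seed = config$seed)
    models <- built$models; vocab <- built$vocab
  } else if (is.null(vocab)) {
    vocab <- dataset_vocab(items)
  }
  modalities <- names(models)
  all_params <- unlist(lapply(models, vq_parameters), recursive = FALSE)
  opt <- .adamw_init(all_params)
  set.seed(config$seed)
  n <- length(items)
  bs <- min(config$batch_size, n)
  n_batches <- max(1L, n %/% bs)
  total_steps <- config$epochs * n_batches
  hist <- vector("list", total_steps)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * bs + 1L):(b * bs)]
      lr <- lr_schedule(step, total_steps, config)
      losses <- list(); row <- list(step = step + 1L, epoch = ep, lr = lr)
      for (m in modalities) {
        batch <- .stage1_batch(items, idx, vocab, m)
        itc <- itc_loss(models[[m]], batch)
        negs <- mine_hard_negatives(itc$sim)
        itm <- itm_loss(models[[m]], itm_pairs(batch, negs))
        itg_nodes <- lapply(seq_along(idx), function(i) {
          itg_loss(models[[m]], batch$embeddings[[i]], batch$texts[[i]])$loss
        })
        itg <- ad_scale(ad_sum_scalars(itg_nodes), 1 / length(idx))
        losses[[m]] <- list(itc$loss, itm$loss, itg)
        row[[paste0(m, "_itc")]] <- as.numeric(ad_val(itc$loss))
        row[[paste0(m, "_itm")]] <- as.numeric(ad_val(itm$loss))
        row[[paste0(m, "_itg")]] <- as.numeric(ad_val(itg))
        row[[paste0(m, "_retrieval")]] <- in_batch_retrieval(itc$sim)
      }
      total <- stage1_total_loss(losses)
      row$total <- as.numeric(ad_val(total))
      ad_zero_grads(all_params)
      ad_backward(total)
      row$grad_norm <- clip_global_norm(all_params, config$clip_norm)
      opt <- .adamw_step(all_params, opt, lr, config$weight_decay)
      step <- step + 1L
      hist[[step]] <- row
    }
  }
  history <- do.call(rbind, lapply(hist, function(r) as.data.frame(r)))
  list(models = models, vocab = vocab, history = history, config = config)
}

#' In-batch retrieval accuracy of trained models over a dataset
#'
#' @param model a `qformer`.
#' @param items generated items.
#' @param vocab caption vocabulary.
#' @param modality which embedding to use.
#' @param batch_size evaluation batch size (chance level = 1/batch_size).
#' @export
eval_retrieval <- function(model, items, vocab, modality, batch_size = 16L) {
  n <- length(items)
  bs <- min(batch_size, n)
  accs <- vapply(seq_len(n %/% bs), function(b) {
    idx <- ((b - 1L) * bs + 1L):(b * bs)
    batch <- .stage1_batch(items, idx, vocab, modality)
    in_batch_retrieval(itc_loss(model, batch)$sim)
  }, numeric(1))
  mean(accs)
}

# dispatch fusion for either the master model or the no-master projector
.fuse_any <- function(fusion, modality_tokens, instr_ids, graph = FALSE) {
  if (inherits(fusion, "master_qformer")) {
    fuse(fusion, modality_tokens, instr_ids, graph = graph)
  } else if (inherits(fusion, "prefix_projector")) {
    parts <- lapply(seq_along(modality_tokens), function(i) {
      tok <- modality_tokens[[i]]
      if (!ad_is(tok)) tok <- ad_const(tok)
      ad_linear(tok, fusion$params[[i]]$W, fusion$params[[i]]$b)
    })
    out <- if (length(parts) == 1L) parts[[1L]] else ad_rbind(parts)
    if (graph) out else ad_val(out)
  } else stop("unknown fusion object")
}

#' No-master fusion: independent per-modality projections
#'
#' The ablation variant: each modality's Stage-1 tokens are projected
#' straight into decoder space and concatenated, so the prefix has
#' sum(K_i) tokens instead of the master's fixed 32.
#'
#' @param modalities modality names in concatenation order.
#' @param hidden_dim Stage-1 token width.
#' @param decoder_dim decoder embedding width.
#' @param seed RNG seed.
#' @export
prefix_projector <- function(modalities, hidden_dim, decoder_dim, seed = 0L) {
  set.seed(seed)
  params <- stats::setNames(lapply(modalities, function(m) {
    list(W = .qf_mat(hidden_dim, decoder_dim, sd = 0.1),
         b = .qf_zeros(decoder_dim))
  }), modalities)
  structure(list(params = params, modalities = modalities),
            class = "prefix_projector")
}

#' Stage-2 training: prefix-conditioned next-token prediction
#'
#' Trains the fusion model, the Stage-1 Q-formers and the output projection
#' with NTP loss on answer tokens only; the decoder must be flagged frozen
#' and is verified bit-identical around the run.
#'
#' @param triples list from [make_field_qa()]: items with `embeddings`,
#'   `prompt_ids`, `answer_ids`.
#' @param models named list of trained Stage-1 `qformer` models.
#' @param fusion a `master_qformer` or [prefix_projector()].
#' @param decoder a [tiny_frozen_decoder()] (must have `frozen = TRUE`).
#' @param config a [train_config()].
#' @return list: `models`, `fusion`, `history`, `decoder_unchanged`
#'   (bitwise check), `config`.
#' @export
train_stage2 <- function(triples, models, fusion, decoder, config) {
  if (!isTRUE(decoder$frozen)) stop("decoder must be frozen before Stage-2 training")
  if (length(triples) < 1L) stop("empty dataset")
  weights_before <- decoder$params
  params <- c(unlist(lapply(models, vq_parameters), recursive = FALSE),
              vq_parameters(fusion))
  opt <- .adamw_init(params)
  set.seed(config$seed)
  n <- length(triples)
  bs <- min(config$batch_size, n)
  n_batches <- max(1L, n %/% bs)
  total_steps <- config$epochs * n_batches
  hist <- vector("list", total_steps)
  step <- 0L
  mods <- names(models)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * bs + 1L):(b * bs)]
      lr <- lr_schedule(step, total_steps, config)
      loss_nodes <- lapply(idx, function(i) {
        tr <- triples[[i]]
        toks <- stats::setNames(lapply(mods, function(m) {
          encode_modality(models[[m]], tr$embeddings[[m]], graph = TRUE)
        }), mods)
        prefix <- .fuse_any(fusion, toks, tr$prompt_ids, graph = TRUE)
        ntp_loss(decoder, assemble_decoder_input(prefix, tr$prompt_ids,
                                                 tr$answer_ids))$loss
      })
      total <- ad_scale(ad_sum_scalars(loss_nodes), 1 / length(idx))
      ad_zero_grads(params)
      ad_backward(total)
      gn <- clip_global_norm(params, config$clip_norm)
      opt <- .adamw_step(params, opt, lr, config$weight_decay)
      step <- step + 1L
      hist[[step]] <- data.frame(step = step, epoch = ep, lr = lr,
                                 loss = as.numeric(ad_val(total)),
                                 grad_norm = gn)
    }
  }
  list(models = models, fusion = fusion,
       history = do.call(rbind, hist),
       decoder_unchanged = identical(weights_before, decoder$params),
       config = config)
}

#' Greedy per-field caption prediction through the frozen decoder
#'
#' @param models Stage-1 models; `fusion` the trained fusion model;
#'   `decoder` the frozen decoder; `vocab` the shared vocabulary.
#' @param embeddings named list of modality embeddings for one variant.
#' @param fields caption fields to predict.
#' @param fusion,decoder,vocab see above.
#' @return caption field list (as in [parse_caption()]).
#' @export
predict_caption <- function(models, fusion, decoder, vocab, embeddings,
                            fields = c("chromosome", "variant_type",
                                       "consequence", "nearest_genes",
                                       "cell_types")) {
  mods <- names(models)
  toks <- stats::setNames(lapply(mods, function(m) {
    encode_modality(models[[m]], embeddings[[m]])
  }), mods)
  eos <- 3L
  out <- list()
  for (fd in fields) {
    prompt <- vq_encode(vocab, paste("predict", fd))
    prefix <- .fuse_any(fusion, toks, prompt)
    ids <- greedy_decode(decoder, prefix, prompt, max_new_tokens = 4L,
                         stop_ids = c(1L, eos))
    words <- vq_decode(vocab, ids)
    out[[fd]] <- if (fd %in% c("nearest_genes", "cell_types")) words
                 else if (length(words) == 0L) NA_character_
                 else words[1L]
  }
  out
}

#' Embedding-permutation ablation
#'
#' Trains two identically initialized Stage-1 runs on the same items: one
#' aligned, one with embeddings derangement-permuted against captions (no
#' item keeps its own embedding). Returns both loss trajectories and final
#' retrieval accuracies; under permutation the contrastive loss cannot fall
#' below chance level and retrieval stays at chance.
#'
#' @param items generated dataset.
#' @param config a [train_config()].
#' @param modality modality to train (single-modality runs keep the
#'   ablation cheap).
#' @param seed permutation seed.
#' @return list: `aligned`, `permuted` (each with `history`, `retrieval`),
#'   `permutation`, `chance`.
#' @export
permutation_ablation <- function(items, config, modality = "sequence",
                                 seed = config$seed) {
  n <- length(items)
  stopifnot(n >= 2L)
  set.seed(seed)
  repeat {
    perm <- sample.int(n)
    if (all(perm != seq_len(n))) break
  }
  vocab <- dataset_vocab(items)
  permuted_items <- lapply(seq_len(n), function(i) {
    it <- items[[i]]
    it$embeddings <- items[[perm[i]]]$embeddings
    it
  })
  attributes(permuted_items) <- attributes(items)
  run <- function(dat) {
    built <- build_stage1_models(dat, modality, vocab, seed = config$seed)
    fit <- train_stage1(dat, config, models = built$models, vocab = vocab)
    list(history = fit$history,
         retrieval = eval_retrieval(fit$models[[modality]], dat, vocab,
                                    modality, config$batch_size),
         models = fit$models)
  }
  list(aligned = run(items), permuted = run(permuted_items),
       permutation = perm, chance = 1 / min(config$batch_size, n))
}

#' Master-model ablation
#'
#' Trains the full Stage-2 stack twice with identical seeds and epochs —
#' once with the master fusion model (32-token prefix) and once with plain
#' per-modality projections (sum(K_i)-token prefix) — and reports per-field
#' caption accuracy of both variants on the same held-out items.
#'
#' @param items generated dataset; split `train_frac`/rest for evaluation.
#' @param config a [train_config()].
#' @param train_frac training fraction.
#' @param fields caption fields for the QA supervision.
#' @param stage1_epochs alignment-pretraining epochs for the Stage-1 models
#'   before Stage 2; both variants start from the identical pretrained
#'   weights (cloned), matching the two-stage regime.
#' @return list: `with_master`, `no_master` (each with `report` and
#'   `prefix_len`), `fields`.
#' @export
master_ablation <- function(items, config, train_frac = 0.8,
                            fields = c("chromosome", "variant_type",
                                       "consequence", "nearest_genes",
                                       "cell_types"),
                            stage1_epochs = 2L) {
  n <- length(items)
  n_train <- max(1L, round(train_frac * n))
  idx_train <- seq_len(n_train)
  idx_eval <- setdiff(seq_len(n), idx_train)
  if (length(idx_eval) == 0L) stop("no held-out items; lower train_frac")
  vocab <- dataset_vocab(items)
  train_items <- items[idx_train]
  attributes(train_items) <- attributes(items)
  qa_train <- make_field_qa(train_items, vocab, fields)
  decoder <- tiny_frozen_decoder(length(vocab), dim = 32L, seed = config$seed)
  gold <- lapply(idx_eval, function(i) items[[i]]$caption$fields)

  base <- build_stage1_models(train_items, vocab = vocab, seed = config$seed)
  if (stage1_epochs > 0L) {
    pre_cfg <- config
    pre_cfg$epochs <- as.integer(stage1_epochs)
    base$models <- train_stage1(train_items, pre_cfg, models = base$models,
                                vocab = vocab)$models
  }

  run_variant <- function(use_master) {
    built <- list(models = lapply(base$models, vq_clone), vocab = vocab)
    fusion <- if (use_master) {
      mcfg <- master_config(decoder_dim = decoder$dim,
                            instr_vocab_size = length(vocab),
                            num_layers = 2L, hidden_dim = 32L, num_heads = 4L)
      master_init(mcfg, seed = config$seed + 100L)
    } else {
      prefix_projector(names(built$models), hidden_dim = 32L,
                       decoder_dim = decoder$dim, seed = config$seed + 100L)
    }
    fit <- train_stage2(qa_train$triples, built$models, fusion, decoder, config)
    preds <- lapply(idx_eval, function(i) {
      predict_caption(fit$models, fit$fusion, decoder, vocab,
                      items[[i]]$embeddings, fields)
    })
    k_total <- sum(vapply(built$models, function(m) m$config$num_queries,
                          integer(1)))
    list(report = per_field_accuracy(preds, gold),
         prefix_len = if (use_master) fusion$config$n_meta else k_total,
         fit = fit)
  }
  list(with_master = run_variant(TRUE), no_master = run_variant(FALSE),
       fields = fields, vocab = vocab, idx_eval = idx_eval)
}
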