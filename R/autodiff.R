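# Reverse-mode automatic differentiation on dense matrices.
#
# Every value in the compute graph is an `ad` node: an environment holding a
# numeric matrix (`val`), an accumulated gradient (`grad`), the parent nodes it
# was computed from, and a closure that maps the node's output gradient to
# per-parent gradients. Scalars are 1x1 matrices. The op set is small and
# fused at the granularity of whole layers (linear, layer norm, multi-head
# attention, cross-entropy) so that graphs stay shallow and fast; each fused
# backward is checked against central finite differences in the test suite.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0L

#' Create an autodiff tensor
#'
#' Wraps a numeric matrix (or vector, promoted to a one-row matrix) as a node
#' in the compute graph.
#'
#' @param val numeric matrix or vector.
#' @param requires_grad logical; should gradients be accumulated here?
#' @return An object of class `ad`.
#' @export
ad_tensor <- function(val, requires_grad = FALSE) {
  if (!is.matrix(val)) val <- matrix(as.numeric(val), nrow = 1L)
  e <- new.env(parent = emptyenv())
  .ad_state$counter <- .ad_state$counter + 1L
  e$id <- .ad_state$counter
  e$val <- val
  e$grad <- NULL
  e$requires <- isTRUE(requires_grad)
  e$parents <- list()
  e$backfn <- NULL
  class(e) <- "ad"
  e
}

#' @rdname ad_tensor
#' @export
ad_const <- function(val) ad_tensor(val, requires_grad = FALSE)

#' @rdname ad_tensor
#' @export
ad_param <- function(val) ad_tensor(val, requires_grad = TRUE)

#' @param x object to test / unwrap.
#' @rdname ad_tensor
#' @export
ad_is <- function(x) inherits(x, "ad")

#' @rdname ad_tensor
#' @export
ad_val <- function(x) if (ad_is(x)) x$val else x

#' @export
print.ad <- function(x, ...) {
  cat(sprintf("<ad %dx%d%s>\n", nrow(x$val), ncol(x$val),
              if (x$requires) " grad" else ""))
  invisible(x)
}

# Internal node constructor. Parents that do not require grad are kept (the
# backfn may read their values) but never traversed.
.ad_node <- function(val, parents, backfn) {
  req <- any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  e <- ad_tensor(val, requires_grad = req)
  if (req) {
    e$parents <- parents
    e$backfn <- backfn
  }
  e
}

# broadcast a length-d vector over the rows of an n x d matrix
.rowbc <- function(x, v) x + rep(v, each = nrow(x))

.ad_accum <- function(p, g) {
  if (is.null(g) || !isTRUE(p$requires)) return(invisible(NULL))
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates `grad` on every reachable node with `requires_grad = TRUE`.
#'
#' @param root an `ad` node holding a 1x1 matrix.
#' @export
ad_backward <- function(root) {
  stopifnot(ad_is(root), length(root$val) == 1L)
  # iterative postorder DFS -> parents-before-children order
  topo <- vector("list", 256L); nt <- 0L
  state <- new.env(hash = TRUE, parent = emptyenv())
  stack <- list(root); ns <- 1L
  while (ns > 0L) {
    e <- stack[[ns]]
    key <- as.character(e$id)
    st <- state[[key]]
    if (is.null(st)) {
      state[[key]] <- 1L
      for (p in e$parents) {
        if (isTRUE(p$requires) && is.null(state[[as.character(p$id)]])) {
          ns <- ns + 1L; stack[[ns]] <- p
        }
      }
    } else if (st == 1L) {
      state[[key]] <- 2L
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- e
      stack[[ns]] <- NULL; ns <- ns - 1L
    } else {
      stack[[ns]] <- NULL; ns <- ns - 1L
    }
  }
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(nt, 1L)) {
    e <- topo[[i]]
    if (is.null(e$backfn) || is.null(e$grad)) next
    gs <- e$backfn(e$grad)
    for (j in seq_along(e$parents)) .ad_accum(e$parents[[j]], gs[[j]])
  }
  invisible(root)
}

#' Zero the gradients of a list of parameters
#' @param params list of `ad` nodes.
#' @export
ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

#' Elementwise and linear-algebra ops on `ad` nodes
#'
#' `ad_add` supports equal shapes or a one-row bias broadcast over rows.
#'
#' @param a,b,x `ad` nodes.
#' @name ad-ops
NULL

#' @rdname ad-ops
#' @export
ad_add <- function(a, b) {
  av <- a$val; bv <- b$val
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- .rowbc(av, as.numeric(bv))
    .ad_node(val, list(a, b), function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else {
    .ad_node(av + bv, list(a, b), function(g) list(g, g))
  }
}

#' @rdname ad-ops
#' @param k plain numeric scalar.
#' @export
ad_scale <- function(a, k) {
  .ad_node(a$val * k, list(a), function(g) list(g * k))
}

#' @rdname ad-ops
#' @export
ad_mul <- function(a, b) {
  stopifnot(all(dim(a$val) == dim(b$val)))
  av <- a$val; bv <- b$val
  .ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' @rdname ad-ops
#' @export
ad_mm <- function(a, b) {
  av <- a$val; bv <- b$val
  .ad_node(av %*% bv, list(a, b), function(g) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

#' @rdname ad-ops
#' @export
ad_t <- function(a) {
  .ad_node(t(a$val), list(a), function(g) list(t(g)))
}

#' @rdname ad-ops
#' @export
ad_exp <- function(a) {
  v <- exp(a$val)
  .ad_node(v, list(a), function(g) list(g * v))
}

#' @rdname ad-ops
#' @param idx integer row indices.
#' @export
ad_rows <- function(a, idx) {
  av <- a$val
  .ad_node(av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    for (i in seq_along(idx)) out[idx[i], ] <- out[idx[i], ] + g[i, ]
    list(out)
  })
}

#' @rdname ad-ops
#' @param xs list of `ad` nodes with equal column counts.
#' @export
ad_rbind <- function(xs) {
  ns <- vapply(xs, function(x) nrow(x$val), integer(1))
  val <- do.call(rbind, lapply(xs, ad_val))
  offs <- cumsum(c(0L, ns))
  .ad_node(val, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      g[(offs[i] + 1L):offs[i + 1L], , drop = FALSE]
    })
  })
}

#' @rdname ad-ops
#' @export
ad_mean_rows <- function(a) {
  n <- nrow(a$val)
  .ad_node(matrix(colMeans(a$val), 1L), list(a), function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

#' @rdname ad-ops
#' @export
ad_sum <- function(a) {
  d <- dim(a$val)
  .ad_node(matrix(sum(a$val), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), d[1L], d[2L]))
  })
}

#' @rdname ad-ops
#' @param s an `ad` node holding a 1x1 scalar multiplier.
#' @export
ad_scalar_mul <- function(a, s) {
  av <- a$val; sv <- as.numeric(s$val)
  .ad_node(av * sv, list(a, s), function(g) {
    list(g * sv, matrix(sum(g * av), 1L, 1L))
  })
}

# ---- fused layer ops -------------------------------------------------------

#' Fused neural-network layer operations
#'
#' These implement whole layers as single graph nodes with hand-written
#' backward passes (verified against finite differences in the tests).
#'
#' @param x,xq,xkv `ad` nodes holding (tokens x features) matrices.
#' @name ad-layers
NULL

#' @rdname ad-layers
#' @param W,b weight / bias `ad` nodes (`b` is 1 x out).
#' @export
ad_linear <- function(x, W, b) {
  xv <- x$val; Wv <- W$val
  val <- .rowbc(xv %*% Wv, as.numeric(b$val))
  .ad_node(val, list(x, W, b), function(g) {
    list(tcrossprod(g, Wv), crossprod(xv, g), matrix(colSums(g), 1L))
  })
}

#' @rdname ad-layers
#' @export
ad_gelu <- function(x) {
  xv <- x$val
  .ad_node(xv * stats::pnorm(xv), list(x), function(g) {
    list(g * (stats::pnorm(xv) + xv * stats::dnorm(xv)))
  })
}

#' @rdname ad-layers
#' @param gamma,beta layer-norm gain and offset (1 x features).
#' @param eps variance floor.
#' @export
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$val
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  sig <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sig
  n <- nrow(xv)
  gv <- as.numeric(gamma$val)
  val <- .rowbc(xhat * rep(gv, each = n), as.numeric(beta$val))
  .ad_node(val, list(x, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxhat <- g * rep(gv, each = n)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sig
    list(dx, dgamma, dbeta)
  })
}

#' @rdname ad-layers
#' @param Wq,bq,Wk,bk,Wv,bv,Wo,bo projection parameters.
#' @param n_heads number of attention heads (must divide the model width).
#' @param mask optional additive attention mask (n_q x n_kv), 0 for allowed
#'   and a large negative number for blocked positions.
#' @export
ad_mha <- function(xq, xkv, Wq, bq, Wk, bk, Wv, bv, Wo, bo,
                   n_heads, mask = NULL) {
  d <- ncol(Wq$val)
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  sc <- 1 / sqrt(dh)
  xqv <- xq$val; xkvv <- xkv$val
  Q <- .rowbc(xqv %*% Wq$val, as.numeric(bq$val))
  K <- .rowbc(xkvv %*% Wk$val, as.numeric(bk$val))
  V <- .rowbc(xkvv %*% Wv$val, as.numeric(bv$val))
  nq <- nrow(Q)
  O <- matrix(0, nq, d)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * sc
    if (!is.null(mask)) S <- S + mask
    S <- S - S[cbind(seq_len(nq), max.col(S, ties.method = "first"))]
    E <- exp(S)
    A <- E / rowSums(E)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  val <- .rowbc(O %*% Wo$val, as.numeric(bo$val))
  .ad_node(val, list(xq, xkv, Wq, bq, Wk, bk, Wv, bv, Wo, bo), function(g) {
    dWo <- crossprod(O, g)
    dbo <- matrix(colSums(g), 1L)
    dO <- tcrossprod(g, Wo$val)
    dQ <- matrix(0, nrow(Q), d)
    dK <- matrix(0, nrow(K), d)
    dV <- matrix(0, nrow(V), d)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- A_list[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- V[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% K[, cols, drop = FALSE]) * sc
      dK[, cols] <- crossprod(dS, Q[, cols, drop = FALSE]) * sc
    }
    dxq <- tcrossprod(dQ, Wq$val)
    dxkv <- tcrossprod(dK, Wk$val) + tcrossprod(dV, Wv$val)
    dWq <- crossprod(xqv, dQ)
    dWk <- crossprod(xkvv, dK)
    dWv <- crossprod(xkvv, dV)
    # when self-attending, xq and xkv are one node; accumulation handles it
    list(dxq, dxkv, dWq, matrix(colSums(dQ), 1L),
         dWk, matrix(colSums(dK), 1L),
         dWv, matrix(colSums(dV), 1L), dWo, dbo)
  })
}

#' @rdname ad-layers
#' @export
ad_l2norm_rows <- function(x) {
  xv <- x$val
  nr <- sqrt(rowSums(xv^2))
  nr[nr == 0] <- 1
  y <- xv / nr
  .ad_node(y, list(x), function(g) {
    list((g - y * rowSums(g * y)) / nr)
  })
}

#' @rdname ad-layers
#' @param K block size: input rows are grouped in consecutive blocks of `K`
#'   and the maximum over each block is taken columnwise.
#' @export
ad_blockmax <- function(x, K) {
  xv <- x$val
  stopifnot(nrow(xv) %% K == 0L)
  B <- nrow(xv) %/% K
  val <- matrix(0, B, ncol(xv))
  arg <- matrix(0L, B, ncol(xv))
  for (i in seq_len(B)) {
    rows <- ((i - 1L) * K + 1L):(i * K)
    blk <- xv[rows, , drop = FALSE]
    w <- max.col(t(blk), ties.method = "first")
    arg[i, ] <- rows[w]
    val[i, ] <- blk[cbind(w, seq_len(ncol(xv)))]
  }
  .ad_node(val, list(x), function(g) {
    out <- matrix(0, nrow(xv), ncol(xv))
    for (i in seq_len(B)) {
      out[cbind(arg[i, ], seq_len(ncol(xv)))] <-
        out[cbind(arg[i, ], seq_len(ncol(xv)))] + g[i, ]
    }
    list(out)
  })
}

#' @rdname ad-layers
#' @param logits `ad` node (n x classes).
#' @param targets integer class indices (1-based); `NA` entries are ignored
#'   (masked out of the mean), mirroring the -100 ignore-index convention.
#' @export
ad_ce_rows <- function(logits, targets) {
  lv <- logits$val
  keep <- which(!is.na(targets))
  if (length(keep) == 0L) {
    return(.ad_node(matrix(0, 1L, 1L), list(logits),
                    function(g) list(matrix(0, nrow(lv), ncol(lv)))))
  }
  m <- lv[cbind(seq_len(nrow(lv)), max.col(lv, ties.method = "first"))]
  E <- exp(lv - m)
  P <- E / rowSums(E)
  picked <- P[cbind(keep, targets[keep])]
  loss <- -mean(log(pmax(picked, 1e-300)))
  .ad_node(matrix(loss, 1L, 1L), list(logits), function(g) {
    gk <- as.numeric(g) / length(keep)
    dl <- matrix(0, nrow(lv), ncol(lv))
    dl[keep, ] <- P[keep, , drop = FALSE] * gk
    dl[cbind(keep, targets[keep])] <- dl[cbind(keep, targets[keep])] - gk
    list(dl)
  })
}

#' Sum a list of scalar `ad` nodes
#' @param xs list of 1x1 `ad` nodes.
#' @export
ad_sum_scalars <- function(xs) {
  val <- sum(vapply(xs, function(x) as.numeric(x$val), numeric(1)))
  .ad_node(matrix(val, 1L, 1L), xs,
           function(g) rep(list(g), length(xs)))
}
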