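# Central finite-difference gradient check for autodiff nodes.
#
# `fn` maps a list of plain matrices to a scalar; `params` is the list of
# matrices to perturb. Returns the maximum absolute deviation between the
# analytic and numeric gradient over all entries.
numeric_grad_gap <- function(fn, params, h = 1e-5) {
  nodes <- lapply(params, ad_param)
  loss <- fn(nodes)
  ad_backward(loss)
  gap <- 0
  for (k in seq_along(params)) {
    g <- nodes[[k]]$grad
    if (is.null(g)) g <- matrix(0, nrow(params[[k]]), ncol(params[[k]]))
    for (i in seq_along(params[[k]])) {
      up <- params; up[[k]][i] <- up[[k]][i] + h
      dn <- params; dn[[k]][i] <- dn[[k]][i] - h
      fu <- as.numeric(fn(lapply(up, ad_const))$val)
      fd <- as.numeric(fn(lapply(dn, ad_const))$val)
      gap <- max(gap, abs((fu - fd) / (2 * h) - g[i]))
    }
  }
  gap
}

rand_mat <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n * m), n, m)
}
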