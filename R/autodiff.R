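# Reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is an environment of class "adnode" holding a numeric
# matrix `val`, an accumulated gradient `grad`, its `parents`, and a `backfn`
# mapping the node's output gradient to a list of parent gradients. Graphs here
# are small (hundreds of residues), so dense matrices and a plain R tape are
# adequate; all heavy lifting is BLAS matrix products.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$n <- 0

new_adnode <- function(val, parents = list(), backfn = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  .ad_counter$n <- .ad_counter$n + 1
  e$id <- .ad_counter$n
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$requires <- requires || any(vapply(parents, function(p) p$requires, logical(1)))
  class(e) <- "adnode"
  e
}

#' @export
#' @method print adnode
print.adnode <- function(x, ...) {
  cat(sprintf("<adnode %dx%d%s>\n", nrow(x$val), ncol(x$val),
              if (x$requires) " grad" else ""))
  invisible(x)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

#' Wrap a constant or parameter on the tape
#'
#' `ad_const()` marks a value no gradient is needed for (inputs, adjacency
#' matrices); `ad_param()` marks a learnable leaf whose gradient is accumulated
#' by [ad_backward()].
#'
#' @param x numeric matrix or vector (vectors become one-column matrices).
#' @return an `adnode`.
#' @keywords internal
ad_const <- function(x) {
  if (inherits(x, "adnode")) return(x)
  new_adnode(as_mat(x))
}

#' @rdname ad_const
#' @keywords internal
ad_param <- function(x) new_adnode(as_mat(x), requires = TRUE)

#' @keywords internal
ad_value <- function(x) if (inherits(x, "adnode")) x$val else x

acc_grad <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Topological order by iterative DFS (recursion would overflow on deep tapes).
topo_order <- function(root) {
  order <- vector("list", 256L); n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L)); n_st <- 1L
  while (n_st > 0L) {
    fr <- stack[[n_st]]
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) { n_st <- n_st - 1L; next }
      seen[[key]] <- TRUE
      stack[[n_st]]$stage <- 2L
      for (p in nd$parents) {
        if (p$requires) { n_st <- n_st + 1L; stack[[n_st]] <- list(node = p, stage = 1L) }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
      n_st <- n_st - 1L
    }
  }
  order[seq_len(n_ord)]
}

#' Run backpropagation from a scalar loss node
#'
#' Accumulates gradients into every upstream [ad_param()] leaf.
#' @param loss an `adnode` holding a 1x1 value.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "adnode"), length(loss$val) == 1L)
  ord <- topo_order(loss)
  loss$grad <- matrix(1, 1, 1)
  for (k in rev(seq_along(ord))) {
    nd <- ord[[k]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      if (!is.null(gs[[i]])) acc_grad(nd$parents[[i]], gs[[i]])
    }
  }
  invisible(loss)
}

# ---- primitive ops ----------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  new_adnode(a$val %*% b$val, list(a, b), function(g) {
    list(g %*% t(b$val), t(a$val) %*% g)
  })
}

# b may be a 1 x d bias row broadcast over the rows of a.
ad_add <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  if (nrow(b$val) == 1L && nrow(a$val) > 1L) {
    new_adnode(sweep(a$val, 2L, b$val[1L, ], "+"), list(a, b), function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else {
    stopifnot(all(dim(a$val) == dim(b$val)))
    new_adnode(a$val + b$val, list(a, b), function(g) list(g, g))
  }
}

ad_sub <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  stopifnot(all(dim(a$val) == dim(b$val)))
  new_adnode(a$val - b$val, list(a, b), function(g) list(g, -g))
}

# Elementwise product; b may be an n x 1 column broadcast across a's columns.
ad_mul <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  if (ncol(b$val) == 1L && ncol(a$val) > 1L) {
    v <- b$val[, 1L]
    new_adnode(a$val * v, list(a, b), function(g) {
      list(g * v, matrix(rowSums(g * a$val), ncol = 1L))
    })
  } else {
    stopifnot(all(dim(a$val) == dim(b$val)))
    new_adnode(a$val * b$val, list(a, b), function(g) {
      list(g * b$val, g * a$val)
    })
  }
}

ad_scale <- function(a, s) {
  a <- ad_const(a)
  new_adnode(a$val * s, list(a), function(g) list(g * s))
}

ad_sigmoid <- function(a) {
  a <- ad_const(a)
  s <- 1 / (1 + exp(-a$val))
  new_adnode(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_silu <- function(a) {
  a <- ad_const(a)
  s <- 1 / (1 + exp(-a$val))
  new_adnode(a$val * s, list(a), function(g) list(g * (s + a$val * s * (1 - s))))
}

ad_tanh <- function(a) {
  a <- ad_const(a)
  t <- tanh(a$val)
  new_adnode(t, list(a), function(g) list(g * (1 - t^2)))
}

ad_concat_cols <- function(nodes) {
  nodes <- lapply(nodes, ad_const)
  widths <- vapply(nodes, function(n) ncol(n$val), integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  new_adnode(do.call(cbind, lapply(nodes, function(n) n$val)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_gather_rows <- function(a, idx) {
  a <- ad_const(a)
  n <- nrow(a$val)
  new_adnode(a$val[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, n, ncol(g))
    # rowsum() collapses duplicate indices correctly
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# Scatter-add rows of a into an n_out-row matrix at positions idx.
ad_scatter_rows <- function(a, idx, n_out) {
  a <- ad_const(a)
  fwd <- function(v) {
    out <- matrix(0, n_out, ncol(v))
    acc <- rowsum(v, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    out
  }
  new_adnode(fwd(a$val), list(a), function(g) list(g[idx, , drop = FALSE]))
}

ad_rowsums <- function(a) {
  a <- ad_const(a)
  new_adnode(matrix(rowSums(a$val), ncol = 1L), list(a), function(g) {
    list(matrix(g[, 1L], nrow(a$val), ncol(a$val)))
  })
}

ad_mean <- function(a) {
  a <- ad_const(a)
  n <- length(a$val)
  new_adnode(matrix(mean(a$val), 1, 1), list(a), function(g) {
    list(matrix(g[1, 1] / n, nrow(a$val), ncol(a$val)))
  })
}

# Softmax of a length-E column of logits within groups (integer labels).
ad_group_softmax <- function(logits, groups) {
  logits <- ad_const(logits)
  x <- logits$val[, 1L]
  mx <- tapply(x, groups, max)[as.character(groups)]
  ex <- exp(x - mx)
  denom <- tapply(ex, groups, sum)[as.character(groups)]
  p <- ex / denom
  new_adnode(matrix(p, ncol = 1L), list(logits), function(g) {
    gi <- g[, 1L]
    dot <- tapply(p * gi, groups, sum)[as.character(groups)]
    list(matrix(p * (gi - dot), ncol = 1L))
  })
}

# Columnwise max over listed member rows, one output row per group.
ad_group_max <- function(a, members) {
  a <- ad_const(a)
  d <- ncol(a$val)
  m <- length(members)
  out <- matrix(0, m, d)
  arg <- matrix(0L, m, d)
  for (i in seq_len(m)) {
    rows <- members[[i]]
    sub <- a$val[rows, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")  # per-column argmax
    arg[i, ] <- rows[w]
    out[i, ] <- sub[cbind(w, seq_len(d))]
  }
  new_adnode(out, list(a), function(g) {
    ga <- matrix(0, nrow(a$val), d)
    for (i in seq_len(m)) {
      ind <- cbind(arg[i, ], seq_len(d))
      ga[ind] <- ga[ind] + g[i, ]
    }
    list(ga)
  })
}

# Per-row layer normalization (no learnable affine).
ad_layernorm <- function(a, eps = 1e-5) {
  a <- ad_const(a)
  d <- ncol(a$val)
  mu <- rowMeans(a$val)
  xc <- a$val - mu
  v <- rowSums(xc^2) / d
  sd_ <- sqrt(v + eps)
  y <- xc / sd_
  new_adnode(y, list(a), function(g) {
    gy <- g / sd_
    list(gy - rowMeans(gy) - y * rowMeans(g * y) / sd_)
  })
}

# Mean cross-entropy of 2-class logits against labels in {0,1}.
ad_softmax_ce <- function(logits, labels) {
  logits <- ad_const(logits)
  z <- logits$val
  m <- pmax(z[, 1L], z[, 2L])
  lse <- m + log(exp(z[, 1L] - m) + exp(z[, 2L] - m))
  logp <- z - lse
  n <- nrow(z)
  pick <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(logp[pick])
  p <- exp(logp)
  new_adnode(matrix(loss, 1, 1), list(logits), function(g) {
    gz <- p
    gz[pick] <- gz[pick] - 1
    list(gz * (g[1, 1] / n))
  })
}

# Row softmax (used for inference probabilities).
ad_softmax_rows <- function(logits) {
  logits <- ad_const(logits)
  z <- logits$val
  mz <- apply(z, 1L, max)
  e <- exp(z - mz)
  p <- e / rowSums(e)
  new_adnode(p, list(logits), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# ---- parameter trees --------------------------------------------------------

# Model weights live in nested named lists of plain matrices. These helpers
# wrap a tree onto the tape, read gradients back in the same shape, and apply
# elementwise updates.

# Non-numeric leaves (layer flags) pass through every helper untouched.

wrap_params <- function(w) {
  if (is.list(w) && !inherits(w, "adnode")) {
    out <- lapply(w, wrap_params)
    attributes(out) <- attributes(w)
    out
  } else if (is.numeric(w)) ad_param(as_mat(w)) else w
}

grads_of <- function(wrapped) {
  if (is.list(wrapped) && !inherits(wrapped, "adnode"))
    return(lapply(wrapped, grads_of))
  if (!inherits(wrapped, "adnode")) return(wrapped)
  if (is.null(wrapped$grad)) matrix(0, nrow(wrapped$val), ncol(wrapped$val)) else wrapped$grad
}

map_params <- function(w, f) {
  if (is.list(w)) lapply(w, map_params, f = f)
  else if (is.numeric(w)) f(w) else w
}

map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map2_params(a[[i]], b[[i]], f)
    attributes(out) <- attributes(a)
    out
  } else if (is.numeric(a)) f(a, b) else a
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = map_params(params, function(x) x * 0),
       v = map_params(params, function(x) x * 0),
       t = 0L)
}

# Classic Adam with L2 regularization folded into the gradient.
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  if (weight_decay > 0) grads <- map2_params(grads, params, function(g, p) g + weight_decay * p)
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mh <- map_params(state$m, function(m) m / (1 - beta1^t))
  vh <- map_params(state$v, function(v) v / (1 - beta2^t))
  step <- map2_params(mh, vh, function(m, v) lr * m / (sqrt(v) + eps))
  params <- map2_params(params, step, function(p, s) p - s)
  list(params = params, state = state)
}
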