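# E(n)-equivariant graph convolutional layer.
#
# One layer jointly updates node scalars H and 3D coordinates X from a routing
# matrix A_route (entry (i,j) = 1 means node i sends to node j; receivers
# aggregate over their in-edges, so directed collapse stages route correctly).
# Scalar outputs are invariant and coordinate outputs equivariant under rigid
# transforms, because coordinates enter messages only through squared
# distances and the coordinate update is a weighted sum of relative vectors.

# Kaiming-style init for a two-layer perceptron.
mlp_init <- function(d_in, d_hidden, d_out, zero_last = FALSE) {
  list(W1 = matrix(stats::rnorm(d_in * d_hidden, sd = sqrt(2 / d_in)), d_in, d_hidden),
       b1 = matrix(0, 1L, d_hidden),
       W2 = if (zero_last) matrix(0, d_hidden, d_out)
            else matrix(stats::rnorm(d_hidden * d_out, sd = sqrt(2 / d_hidden)),
                        d_hidden, d_out),
       b2 = matrix(0, 1L, d_out))
}

mlp_forward <- function(w, x, final_act = FALSE) {
  h <- ad_silu(ad_add(ad_matmul(x, w$W1), w$b1))
  out <- ad_add(ad_matmul(h, w$W2), w$b2)
  if (final_act) ad_silu(out) else out
}

#' Initialize the weights of one equivariant layer
#'
#' The edge network `phi_e` maps `[h_i, h_j, |x_i - x_j|^2]` to a message; the
#' coordinate network `phi_x` maps a message to one scalar edge weight (final
#' layer zero-initialized for stability); the feature network `phi_h` maps
#' `[h_i, aggregated message]` to the additive feature update. The optional
#' attention gate multiplies each message by a sigmoid of a linear map.
#'
#' @param d node feature width.
#' @param use_attention gate messages with a learned scalar in (0,1).
#' @param normalize apply per-row layer normalization to the scalar input and
#'   normalize radial vectors in the coordinate update.
#' @param edge_attr_dim width of optional per-edge attributes fed to the edge
#'   network (default 0; the production model never populates them).
#' @return an `egcl_weights` list.
#' @export
egcl_init <- function(d, use_attention = FALSE, normalize = FALSE,
                      edge_attr_dim = 0L) {
  structure(list(
    phi_e = mlp_init(2L * d + 1L + as.integer(edge_attr_dim), d, d),
    phi_x = mlp_init(d, d, 1L, zero_last = TRUE),
    # zero-init final layers: each layer starts as the identity map, so deep
    # stacks of residual blocks cannot amplify activations before training
    phi_h = mlp_init(2L * d, d, d, zero_last = TRUE),
    att = list(W = matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1L),
               b = matrix(0, 1L, 1L)),
    use_attention = use_attention,
    normalize = normalize
  ), class = "egcl_weights")
}

egcl_split_flags <- function(w) {
  list(params = w[c("phi_e", "phi_x", "phi_h", "att")],
       use_attention = isTRUE(w$use_attention),
       normalize = isTRUE(w$normalize))
}

# Directed edge list of a routing matrix: src sends to dst.
edge_list <- function(A_route) {
  e <- which(A_route != 0, arr.ind = TRUE)
  list(src = as.integer(e[, 1L]), dst = as.integer(e[, 2L]))
}

# In-degree based aggregation constant C = 1/(N-1), guarded to 1 for N <= 1.
recv_coef <- function(A_route) {
  N <- colSums(A_route != 0)
  ifelse(N <= 1, 1, 1 / (N - 1))
}

# Tape-level message computation shared by the exported wrapper and the full
# layer. H, X are adnodes; returns list(msg = adnode (E x d), edges).
.edge_messages <- function(H, X, A_route, w, edge_attr = NULL) {
  fl <- egcl_split_flags(w)
  ed <- edge_list(A_route)
  if (length(ed$src) == 0L) return(list(msg = NULL, edges = ed))
  Hin <- if (fl$normalize) ad_layernorm(H) else H
  hi <- ad_gather_rows(Hin, ed$src)
  hj <- ad_gather_rows(Hin, ed$dst)
  diff <- ad_sub(ad_gather_rows(X, ed$src), ad_gather_rows(X, ed$dst))
  d2 <- ad_rowsums(ad_mul(diff, diff))
  inputs <- list(hi, hj, d2)
  if (!is.null(edge_attr)) {
    ea <- as_mat(edge_attr)
    if (nrow(ea) == nrow(A_route) && ncol(ea) == ncol(A_route)) {
      ea <- matrix(ea[A_route != 0], ncol = 1L)  # one scalar per (src, dst)
    } else if (nrow(ea) != length(ed$src)) {
      stop("edge_attr must be n x n or one row per routed edge", call. = FALSE)
    }
    inputs <- c(inputs, list(ad_const(ea)))
  }
  msg <- mlp_forward(fl$params$phi_e, ad_concat_cols(inputs),
                     final_act = TRUE)
  if (fl$use_attention) {
    gate <- ad_sigmoid(ad_add(ad_matmul(msg, fl$params$att$W), fl$params$att$b))
    msg <- ad_mul(msg, gate)
  }
  list(msg = msg, edges = ed)
}

#' Compute per-edge messages
#'
#' Evaluates the edge network on every ordered pair `(i -> j)` with
#' `A_route[i, j] = 1`. Coordinates enter only through the squared distance,
#' so messages are invariant to rigid transforms.
#'
#' @param H n x d node features.
#' @param X n x 3 node coordinates.
#' @param A_route n x n binary routing matrix (possibly asymmetric).
#' @param weights an `egcl_weights`.
#' @param edge_attr optional edge attributes: an n x n matrix (one scalar per
#'   ordered pair) or one row per routed edge; appended to the edge-network
#'   input (requires matching `edge_attr_dim` at [egcl_init()]).
#' @return list with `messages` (E x d matrix), `src`, `dst` (edge endpoints).
#' @export
edge_messages <- function(H, X, A_route, weights, edge_attr = NULL) {
  H <- as_mat(H)
  if (nrow(H) != nrow(A_route))
    stop("H and A_route disagree on node count", call. = FALSE)
  out <- .edge_messages(ad_const(H), ad_const(as_mat(X)), A_route, weights,
                        edge_attr = edge_attr)
  list(messages = if (is.null(out$msg)) matrix(0, 0L, ncol(H)) else out$msg$val,
       src = out$edges$src, dst = out$edges$dst)
}

.update_coords <- function(X, msg, edges, A_route, w) {
  fl <- egcl_split_flags(w)
  n <- nrow(A_route)
  if (is.null(msg) || length(edges$src) == 0L) return(X)
  diff <- ad_sub(ad_gather_rows(X, edges$dst), ad_gather_rows(X, edges$src))
  if (fl$normalize) {
    nrm <- sqrt(rowSums((ad_value(diff))^2)) + 1
    diff <- ad_mul(diff, ad_const(matrix(1 / nrm, ncol = 1L)))
  }
  wgt <- mlp_forward(fl$params$phi_x, msg)          # E x 1
  contrib <- ad_mul(diff, wgt)
  agg <- ad_scatter_rows(contrib, edges$dst, n)
  agg <- ad_mul(agg, ad_const(matrix(recv_coef(A_route), ncol = 1L)))
  ad_add(X, agg)
}

#' Update coordinates from edge messages
#'
#' Each receiving node moves along the weighted sum of its incoming relative
#' vectors `x_i - x_j`, scaled by `1/(N-1)` for in-degree `N` (1 when
#' `N <= 1`). Nodes with no in-edges are unchanged.
#'
#' @inheritParams edge_messages
#' @param messages result of [edge_messages()] on the same routing matrix.
#' @return n x 3 matrix of updated coordinates.
#' @export
update_coords <- function(X, messages, A_route, weights) {
  out <- .update_coords(ad_const(as_mat(X)),
                        if (nrow(messages$messages) > 0L)
                          ad_const(messages$messages) else NULL,
                        messages, A_route, weights)
  ad_value(out)
}

.update_features <- function(H, msg, edges, A_route, w) {
  fl <- egcl_split_flags(w)
  n <- nrow(A_route)
  Hin <- if (fl$normalize) ad_layernorm(H) else H
  if (is.null(msg) || length(edges$src) == 0L) {
    agg <- ad_const(matrix(0, n, ncol(H$val)))
  } else {
    agg <- ad_scatter_rows(msg, edges$dst, n)
    agg <- ad_mul(agg, ad_const(matrix(recv_coef(A_route), ncol = 1L)))
  }
  upd <- mlp_forward(fl$params$phi_h, ad_concat_cols(list(Hin, agg)))
  ad_add(H, upd)
}

#' Update node features from aggregated messages
#'
#' The incoming messages of each node are averaged with the `1/(N-1)`
#' convention, concatenated with the node's own state, passed through the
#' feature network and added as a residual.
#'
#' @param H n x d node features.
#' @inheritParams update_coords
#' @return n x d matrix of updated features.
#' @export
update_features <- function(H, messages, A_route, weights) {
  out <- .update_features(ad_const(as_mat(H)),
                          if (nrow(messages$messages) > 0L)
                            ad_const(messages$messages) else NULL,
                          messages, A_route, weights)
  ad_value(out)
}

# Tape-level full layer; state is list(H = adnode, X = adnode).
# update_x = FALSE freezes coordinates (scalars still update).
.egcl_forward <- function(state, A_route, w, update_x = TRUE) {
  em <- .edge_messages(state$H, state$X, A_route, w)
  list(H = .update_features(state$H, em$msg, em$edges, A_route, w),
       X = if (update_x) .update_coords(state$X, em$msg, em$edges, A_route, w)
           else state$X)
}

#' Run one equivariant layer
#'
#' Composes message computation, coordinate update and feature update. Scalar
#' outputs are E(3)-invariant; coordinate outputs are E(3)-equivariant.
#'
#' @param state list with `H` (n x d) and `X` (n x 3).
#' @param A_route n x n binary routing matrix.
#' @param weights an `egcl_weights`.
#' @return list with updated `H` and `X`.
#' @export
egcl_forward <- function(state, A_route, weights) {
  out <- .egcl_forward(list(H = ad_const(as_mat(state$H)),
                            X = ad_const(as_mat(state$X))), A_route, weights)
  list(H = ad_value(out$H), X = ad_value(out$X))
}
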