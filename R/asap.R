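# Adaptive structure-aware pooling: soft clusters, master-to-token attention,
# local-extreme-convolution scoring and top-fraction node selection.

#' Soft clusters by hop neighbourhood
#'
#' Every node is the centre of a cluster containing all nodes within `hop`
#' edges of it (itself included), computed by breadth-first expansion.
#'
#' @param A n x n binary symmetric adjacency.
#' @param hop neighbourhood radius in edges (default 1).
#' @return a `cluster_set`: list with `hop` and `members` (list of sorted
#'   integer vectors, one per node).
#' @export
soft_cluster <- function(A, hop = 1) {
  stopifnot(hop >= 1)
  n <- nrow(A)
  members <- lapply(seq_len(n), function(i) {
    frontier <- i; seen <- logical(n); seen[i] <- TRUE
    for (k in seq_len(hop)) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] != 0))))
      nxt <- nxt[!seen[nxt]]
      if (length(nxt) == 0L) break
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    which(seen)
  })
  structure(list(hop = hop, members = members), class = "cluster_set")
}

# Flat (cluster, member) pair representation used by the tape ops.
cluster_pairs <- function(clusters) {
  lens <- lengths(clusters$members)
  list(cluster = rep.int(seq_along(clusters$members), lens),
       member = unlist(clusters$members, use.names = FALSE))
}

#' Initialize pooling weights
#'
#' Contains the independent equivariant layer whose output drives scoring, the
#' additive-attention parameters (`W`: d x 2d applied to the concatenated
#' master query and member state, `w_vec`: length d), and the three LEConv
#' matrices plus the length-d projection reducing the scored vector to a
#' scalar.
#'
#' @param d feature width.
#' @return an `asap_weights` list.
#' @export
asap_init <- function(d) {
  sd0 <- sqrt(1 / d)
  structure(list(
    egcl = egcl_init(d, use_attention = FALSE, normalize = FALSE),
    att = list(W = matrix(stats::rnorm(2L * d * d, sd = sd0), 2L * d, d),
               w_vec = matrix(stats::rnorm(d, sd = sd0), d, 1L)),
    leconv = list(W1 = matrix(stats::rnorm(d * d, sd = sd0), d, d),
                  W2 = matrix(stats::rnorm(d * d, sd = sd0), d, d),
                  W3 = matrix(stats::rnorm(d * d, sd = sd0), d, d),
                  proj = matrix(stats::rnorm(d, sd = sd0), d, 1L))
  ), class = "asap_weights")
}

# ---- tape-level stages ------------------------------------------------------

.master_query <- function(H_prime, clusters) {
  ad_group_max(H_prime, clusters$members)
}

.m2t_attention <- function(m, H_prime, clusters, att) {
  pr <- cluster_pairs(clusters)
  mi <- ad_gather_rows(m, pr$cluster)
  hj <- ad_gather_rows(H_prime, pr$member)
  z <- ad_sigmoid(ad_matmul(ad_concat_cols(list(mi, hj)), att$W))
  logits <- ad_matmul(z, att$w_vec)
  ad_group_softmax(logits, pr$cluster)
}

.cluster_features <- function(alpha, H, clusters) {
  pr <- cluster_pairs(clusters)
  hj <- ad_gather_rows(H, pr$member)
  ad_scatter_rows(ad_mul(hj, alpha), pr$cluster, nrow(ad_value(H)))
}

.leconv_score <- function(Hc, A, lw) {
  deg <- matrix(rowSums(A != 0), ncol = 1L)
  self_term <- ad_matmul(Hc, lw$W1)
  own <- ad_mul(ad_matmul(Hc, lw$W2), ad_const(deg))
  nbr <- ad_matmul(ad_const(A), ad_matmul(Hc, lw$W3))
  ad_matmul(ad_sigmoid(ad_sub(ad_add(self_term, own), nbr)), lw$proj)
}

# ---- exported numeric wrappers ---------------------------------------------

#' Master query of each cluster
#'
#' Elementwise maximum of the transformed node states over each cluster's
#' members: the "public information" of the cluster.
#'
#' @param H_prime n x d matrix (output of the pooling layer's own equivariant
#'   convolution).
#' @param clusters a `cluster_set`.
#' @return n x d matrix.
#' @export
master_query <- function(H_prime, clusters) {
  ad_value(.master_query(ad_const(as_mat(H_prime)), clusters))
}

#' Master-to-token additive attention
#'
#' For each cluster, the master query attends to every member; the attention
#' logit is `w_vec' * sigmoid(W [m_i || h'_j])` and weights are softmaxed
#' within the cluster, so they sum to one per cluster.
#'
#' @inheritParams master_query
#' @param m n x d master-query matrix.
#' @param W 2d x d attention map applied to the concatenation.
#' @param w_vec length-d scoring vector.
#' @return list with `alpha` (one weight per (cluster, member) pair),
#'   `cluster`, `member` (pair indices).
#' @export
m2t_attention <- function(m, H_prime, clusters, W, w_vec) {
  att <- list(W = as_mat(W), w_vec = as_mat(w_vec))
  pr <- cluster_pairs(clusters)
  a <- ad_value(.m2t_attention(ad_const(as_mat(m)), ad_const(as_mat(H_prime)),
                               clusters, att))
  list(alpha = a[, 1L], cluster = pr$cluster, member = pr$member)
}

#' Attention-weighted cluster features
#'
#' `h^c_i = sum_j alpha_ij h_j` over the members of cluster `i`; the weights
#' come from the transformed states but are applied to the raw features.
#'
#' @param alpha result of [m2t_attention()].
#' @param H n x d raw node features.
#' @param clusters a `cluster_set`.
#' @return n x d matrix.
#' @export
cluster_features <- function(alpha, H, clusters) {
  ad_value(.cluster_features(ad_const(matrix(alpha$alpha, ncol = 1L)),
                             ad_const(as_mat(H)), clusters))
}

#' Local-extreme-convolution node scores
#'
#' `phi_i = sigmoid(h^c_i W1 + sum_j A_ij (h^c_i W2 - h^c_j W3))` reduced to a
#' scalar by a learnable length-d projection. High scores mark nodes whose
#' cluster features stand out from their neighbourhood.
#'
#' @param Hc n x d cluster feature matrix.
#' @param A n x n adjacency.
#' @param W1,W2,W3 d x d weight matrices.
#' @param proj length-d reduction vector.
#' @return numeric length-n score vector.
#' @export
leconv_score <- function(Hc, A, W1, W2, W3, proj) {
  lw <- list(W1 = as_mat(W1), W2 = as_mat(W2), W3 = as_mat(W3),
             proj = as_mat(proj))
  ad_value(.leconv_score(ad_const(as_mat(Hc)), A, lw))[, 1L]
}

# Indices of the ceiling(ratio * n) largest scores, at least one. Ties break
# toward lower node indices; ranking uses scores rounded at 1e-9 so that
# floating-point noise (e.g. from a rigidly transformed structure) can never
# reorder genuinely tied nodes.
top_fraction_idx <- function(Phi, ratio) {
  if (!(ratio > 0 && ratio <= 1))
    stop("`ratio` must lie in (0, 1]", call. = FALSE)
  n <- length(Phi)
  k <- max(1L, ceiling(ratio * n))
  sort(order(-round(Phi, 9), seq_len(n))[seq_len(k)])
}

#' Select the top-scoring fraction of nodes and pool
#'
#' Keeps the `ceiling(ratio * n)` highest-scoring nodes (at least one; ties
#' broken by lower index), gates their features by their scores (the step that
#' makes the pooling parameters learnable), and restricts the adjacency to the
#' kept nodes while preserving the original node indexing.
#'
#' @param H n x d node features.
#' @param X n x 3 coordinates.
#' @param A n x n adjacency.
#' @param Phi length-n score vector.
#' @param ratio sampling ratio in (0, 1] (default 0.30).
#' @return a `pool_selection`: `idx` (sorted kept indices), `scores`,
#'   `H_pool` (|idx| x d, gated), `A_pool` (n x n, zero outside idx),
#'   `A_pool_compact` (|idx| x |idx|), `X_pool`.
#' @export
select_and_pool <- function(H, X, A, Phi, ratio = 0.30) {
  H <- as_mat(H); X <- as_mat(X)
  n <- nrow(H)
  idx <- top_fraction_idx(Phi, ratio)
  gated <- H * Phi
  A_pool <- matrix(0, n, n)
  A_pool[idx, idx] <- A[idx, idx]
  structure(list(idx = idx, scores = Phi,
                 H_pool = gated[idx, , drop = FALSE],
                 A_pool = A_pool,
                 A_pool_compact = A[idx, idx, drop = FALSE],
                 X_pool = X[idx, , drop = FALSE]),
            class = "pool_selection")
}

#' Run the full pooling module
#'
#' Applies the module's own equivariant layer to obtain transformed states,
#' forms soft clusters, master queries and attention weights, scores nodes by
#' local-extreme convolution and selects the top fraction.
#'
#' @param H n x d features.
#' @param X n x 3 coordinates.
#' @param A n x n adjacency.
#' @param weights an `asap_weights`.
#' @param ratio sampling ratio in (0, 1].
#' @param hop cluster radius.
#' @return a `pool_selection` (see [select_and_pool()]); also carries the
#'   attention pairs as attribute `"attention"`.
#' @export
asap_pool <- function(H, X, A, weights, ratio = 0.30, hop = 1) {
  H <- as_mat(H)
  clusters <- soft_cluster(A, hop)
  hp <- egcl_forward(list(H = H, X = as_mat(X)), A, weights$egcl)$H
  m <- master_query(hp, clusters)
  alpha <- m2t_attention(m, hp, clusters, weights$att$W, weights$att$w_vec)
  Hc <- cluster_features(alpha, H, clusters)
  Phi <- leconv_score(Hc, A, weights$leconv$W1, weights$leconv$W2,
                      weights$leconv$W3, weights$leconv$proj)
  sel <- select_and_pool(H, X, A, Phi, ratio)
  attr(sel, "attention") <- alpha
  sel
}

# Tape-level pooling used inside the trainable model: returns Phi as an adnode
# plus the discrete selection made from its values.
.asap_scores <- function(Hn, Xn, A, w, hop) {
  clusters <- soft_cluster(A, hop)
  hp <- .egcl_forward(list(H = Hn, X = Xn), A, w$egcl)$H
  m <- .master_query(hp, clusters)
  alpha <- .m2t_attention(m, hp, clusters, w$att)
  Hc <- .cluster_features(alpha, Hn, clusters)
  .leconv_score(Hc, A, w$leconv)
}
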