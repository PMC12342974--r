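# Independent brute-force oracles used across the suite. These deliberately
# use plain loops and closed forms, never the package's vectorized paths.

# The matrix tape is internal API; alias what the gradient tests exercise.
for (nm in c("ad_param", "ad_const", "ad_backward", "ad_value", "ad_mean",
             "ad_matmul", "ad_mul", "ad_add", "ad_sub", "ad_silu",
             "ad_sigmoid", "ad_tanh", "ad_gather_rows", "ad_scatter_rows",
             "ad_rowsums", "ad_concat_cols", "ad_layernorm",
             "ad_group_softmax", "ad_group_max", "ad_softmax_ce",
             "ad_softmax_rows", "adam_init", "adam_step", "wrap_params",
             "grads_of", "with_seed")) {
  assign(nm, getFromNamespace(nm, "sitecollapse"))
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(X, Q, t) {
  sweep(X %*% t(Q), 2L, t, "+")
}

# O(n^2) loop adjacency
brute_adjacency <- function(coords, threshold) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= threshold)
      A[i, j] <- 1
  }
  A
}

# Pairwise-count AUROC (ties count 1/2)
brute_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Step-wise precision-recall summation over distinct thresholds
brute_auprc <- function(labels, scores) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in th) {
    calls <- scores >= t
    tp <- sum(calls & labels == 1)
    prec <- tp / sum(calls)
    rec <- tp / P
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))
silu_ <- function(x) x * sigmoid_(x)

# Plain numeric two-layer perceptron matching the layer networks
mlp_eval <- function(w, x, final_act = FALSE) {
  h <- silu_(sweep(x %*% w$W1, 2L, w$b1[1L, ], "+"))
  out <- sweep(h %*% w$W2, 2L, w$b2[1L, ], "+")
  if (final_act) silu_(out) else out
}

# Loop-based single-layer oracle: messages, coordinate and feature updates
# computed edge-by-edge and node-by-node.
brute_egcl <- function(H, X, A_route, w) {
  n <- nrow(H)
  Hin <- H
  if (isTRUE(w$normalize)) {
    Hin <- t(apply(H, 1L, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  }
  msgs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (A_route[i, j] != 0) {
      d2 <- sum((X[i, ] - X[j, ])^2)
      m <- mlp_eval(w$phi_e, cbind(rbind(Hin[i, ]), rbind(Hin[j, ]), d2)[1, , drop = FALSE],
                    final_act = TRUE)
      if (isTRUE(w$use_attention))
        m <- m * sigmoid_(sum(m * w$att$W[, 1L]) + w$att$b[1L, 1L])
      msgs[[length(msgs) + 1L]] <- list(i = i, j = j, m = m)
    }
  }
  Xo <- X; Ho <- H
  for (v in seq_len(n)) {
    inc <- Filter(function(e) e$j == v, msgs)
    N <- length(inc)
    C <- if (N <= 1) 1 else 1 / (N - 1)
    dx <- c(0, 0, 0)
    agg <- matrix(0, 1L, ncol(H))
    for (e in inc) {
      diffv <- X[v, ] - X[e$i, ]
      if (isTRUE(w$normalize)) diffv <- diffv / (sqrt(sum(diffv^2)) + 1)
      dx <- dx + diffv * mlp_eval(w$phi_x, e$m)[1L, 1L]
      agg <- agg + e$m
    }
    Xo[v, ] <- X[v, ] + C * dx
    upd <- mlp_eval(w$phi_h, cbind(rbind(Hin[v, ]), C * agg))
    Ho[v, ] <- H[v, ] + upd[1L, ]
  }
  list(H = Ho, X = Xo)
}

# Random small test graph with coordinates and features
random_graph <- function(n, d, p_edge = 0.4) {
  A <- matrix(0, n, n)
  if (n > 1) {
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p_edge)
    A <- A + t(A)
  }
  list(A = A, H = matrix(rnorm(n * d), n, d), X = matrix(rnorm(n * 3, sd = 3), n, 3))
}

# Central finite difference of f at x (scalar-valued f, matrix x)
finite_diff <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    g[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small deterministic dataset for model-level tests
tiny_dataset <- function(n_proteins = 3, len = c(16, 24), seed = 42,
                         signal = 0.9) {
  generate_dataset(n_proteins, len, seed = seed, signal_strength = signal)
}
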