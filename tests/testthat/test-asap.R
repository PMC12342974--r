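# Structure-aware pooling: clusters, attention, scoring, selection.

test_that("soft clusters equal boolean matrix-power reachability", {
  # hand cases
  A0 <- matrix(0, 3, 3)
  cl0 <- soft_cluster(A0, 1)
  expect_identical(cl0$members, as.list(1:3))
  path <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_identical(soft_cluster(path, 1)$members[[2]], 1:3)
  # random graphs vs (A + I)^hop > 0
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    g <- random_graph(n, 2)
    for (hop in 1:2) {
      M <- diag(n) + g$A
      R <- diag(n)
      for (k in seq_len(hop)) R <- R %*% M
      cl <- soft_cluster(g$A, hop)
      for (i in seq_len(n))
        expect_identical(cl$members[[i]], which(R[i, ] > 0))
    }
  }
})

test_that("master query is the elementwise cluster maximum", {
  hp <- rbind(c(1, -2), c(0, 5))
  A <- rbind(c(0, 1), c(1, 0))
  m <- master_query(hp, soft_cluster(A, 1))
  expect_equal(m[1, ], c(1, 5))
  # singleton cluster returns the node's own state
  m0 <- master_query(hp, soft_cluster(matrix(0, 2, 2), 1))
  expect_equal(m0, hp)
  # random case vs loop oracle
  set.seed(42)
  g <- random_graph(8, 4)
  cl <- soft_cluster(g$A, 1)
  m2 <- master_query(g$H, cl)
  for (i in 1:8)
    expect_equal(m2[i, ], apply(g$H[cl$members[[i]], , drop = FALSE], 2, max))
})

test_that("attention weights are a within-cluster softmax of additive scores", {
  set.seed(43)
  d <- 4; n <- 7
  g <- random_graph(n, d)
  cl <- soft_cluster(g$A, 1)
  W <- matrix(rnorm(2 * d * d), 2 * d, d)
  wv <- rnorm(d)
  m <- master_query(g$H, cl)
  att <- m2t_attention(m, g$H, cl, W, wv)
  # rows sum to one per cluster
  sums <- tapply(att$alpha, att$cluster, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # loop-based softmax oracle
  for (i in seq_len(n)) {
    mem <- cl$members[[i]]
    logits <- vapply(mem, function(j)
      sum(wv * sigmoid_(c(m[i, ], g$H[j, ]) %*% W)), numeric(1))
    p <- exp(logits - max(logits)); p <- p / sum(p)
    expect_equal(att$alpha[att$cluster == i], p, tolerance = 1e-6)
  }
  # two members with identical states split the weight evenly
  H2 <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 1))
  A2 <- rbind(c(0, 1), c(1, 0))
  cl2 <- soft_cluster(A2, 1)
  att2 <- m2t_attention(master_query(H2, cl2), H2, cl2, W, wv)
  expect_equal(att2$alpha, rep(0.5, 4), tolerance = 1e-9)
})

test_that("cluster features combine raw states under the attention weights", {
  set.seed(44)
  g <- random_graph(6, 3)
  cl <- soft_cluster(g$A, 1)
  W <- matrix(rnorm(6 * 3), 6, 3); wv <- rnorm(3)
  m <- master_query(g$H, cl)
  att <- m2t_attention(m, g$H, cl, W, wv)
  Hc <- cluster_features(att, g$H, cl)
  for (i in 1:6) {
    mem <- cl$members[[i]]
    a <- att$alpha[att$cluster == i]
    expect_equal(Hc[i, ], colSums(g$H[mem, , drop = FALSE] * a),
                 tolerance = 1e-9)
  }
  # uniform weights over a cluster give the member mean
  ones <- list(alpha = rep(1 / 3, 3), cluster = rep(1L, 3), member = 1:3)
  cl1 <- structure(list(hop = 1L, members = list(1:3, 2L, 3L)),
                   class = "cluster_set")
  ones$cluster <- rep(1L, 3); ones$member <- 1:3
  # restrict to the first cluster only
  Hc1 <- cluster_features(list(alpha = c(rep(1 / 3, 3), 1, 1),
                               cluster = c(1L, 1L, 1L, 2L, 3L),
                               member = c(1L, 2L, 3L, 2L, 3L)),
                          g$H[1:3, ], cl1)
  expect_equal(Hc1[1, ], colMeans(g$H[1:3, ]), tolerance = 1e-9)
})

test_that("local-extreme scores match the loop oracle and its degenerate cases", {
  set.seed(45)
  d <- 4
  g <- random_graph(6, d)
  W1 <- matrix(rnorm(d * d), d); W2 <- matrix(rnorm(d * d), d)
  W3 <- matrix(rnorm(d * d), d); pr <- rnorm(d)
  Hc <- g$H
  phi <- leconv_score(Hc, g$A, W1, W2, W3, pr)
  for (i in 1:6) {
    nbr <- which(g$A[i, ] != 0)
    acc <- Hc[i, ] %*% W1
    for (j in nbr) acc <- acc + Hc[i, ] %*% W2 - Hc[j, ] %*% W3
    expect_equal(phi[i], sum(sigmoid_(acc) * pr), tolerance = 1e-6)
  }
  # isolated node: neighbour sum is empty
  A0 <- matrix(0, 6, 6)
  phi0 <- leconv_score(Hc, A0, W1, W2, W3, pr)
  expect_equal(phi0[1], sum(sigmoid_(Hc[1, ] %*% W1) * pr), tolerance = 1e-9)
  # identical features and W2 = W3: the neighbour term cancels
  Hs <- matrix(1, 6, d)
  phis <- leconv_score(Hs, g$A, W1, W2, W2, pr)
  expect_equal(phis, rep(phi0 <- sum(sigmoid_(Hs[1, ] %*% W1) * pr), 6),
               tolerance = 1e-9)
})

test_that("top-fraction selection sizes, ties and gating follow the contract", {
  H <- matrix(1, 10, 2); X <- matrix(0, 10, 3)
  A <- matrix(1, 10, 10); diag(A) <- 0
  sel <- select_and_pool(H, X, A, Phi = 10:1, ratio = 0.30)
  expect_identical(sel$idx, 1:3)           # ceil(0.3*10) = 3 kept
  expect_equal(nrow(sel$H_pool), 3L)
  expect_equal(sel$H_pool[, 1], c(10, 9, 8))  # score gating
  # ratio 1 keeps everything and the adjacency intact
  sel1 <- select_and_pool(H, X, A, Phi = rnorm(10), ratio = 1)
  expect_identical(sel1$idx, 1:10)
  expect_identical(sel1$A_pool, A)
  # equal scores break ties toward lower indices
  selt <- select_and_pool(H, X, A, Phi = rep(2, 10), ratio = 0.45)
  expect_identical(selt$idx, 1:5)
  # floor of one node
  self <- select_and_pool(H[1:3, ], X[1:3, ], A[1:3, 1:3], c(1, 2, 3), 0.01)
  expect_identical(self$idx, 3L)
  expect_error(select_and_pool(H, X, A, 10:1, ratio = 0), "ratio")
  expect_error(select_and_pool(H, X, A, 10:1, ratio = 1.2), "ratio")
})

test_that("pooled adjacency keeps only edges among sampled nodes", {
  set.seed(46)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    g <- random_graph(n, 3)
    phi <- rnorm(n)
    sel <- select_and_pool(g$H, g$X, g$A, phi, 0.5)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      expected <- if (i %in% sel$idx && j %in% sel$idx) g$A[i, j] else 0
      expect_identical(sel$A_pool[i, j], expected)
    }
    expect_identical(sel$A_pool_compact, g$A[sel$idx, sel$idx])
  }
})

test_that("pooling scores are invariant to rigid transforms of the structure", {
  set.seed(47)
  g <- random_graph(9, 5)
  w <- with_seed(48, function() asap_init(5))
  sel <- asap_pool(g$H, g$X, g$A, w)
  for (k in 1:5) {
    Xr <- apply_rigid(g$X, random_rotation(), rnorm(3, sd = 6))
    sel2 <- asap_pool(g$H, Xr, g$A, w)
    expect_equal(sel$scores, sel2$scores, tolerance = 1e-6)
    expect_identical(sel$idx, sel2$idx)
  }
})

test_that("gated pooled features carry gradient into the scoring parameters", {
  # finite-difference sensitivity of an H_pool entry w.r.t. a LEConv weight
  set.seed(49)
  g <- random_graph(7, 4)
  w <- with_seed(50, function() asap_init(4))
  f <- function(w1_11) {
    w2 <- w
    w2$leconv$W1[1, 1] <- w1_11
    sel <- asap_pool(g$H, g$X, g$A, w2, ratio = 0.5)
    sum(sel$H_pool)
  }
  x0 <- w$leconv$W1[1, 1]
  fd <- (f(x0 + 1e-4) - f(x0 - 1e-4)) / 2e-4
  expect_gt(abs(fd), 1e-8)
})
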