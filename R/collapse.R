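# Four-stage graph collapse and unpooling.
#
# One block routes messages through four directed stages: (1) the original
# graph, (2) unsampled nodes into the sampled subgraph, (3) within the
# subgraph, (4) the subgraph back out (the transpose of stage 2). Distant
# residues thereby exchange information once per block through sampled hubs.

#' Build the four stage-routing matrices
#'
#' Entry `(i, j) = 1` means node `i` sends to node `j`. Stage 1 is the full
#' adjacency; stage 2 keeps edges whose receiver is sampled and whose sender
#' is not; stage 3 is the adjacency restricted to sampled nodes; stage 4 is
#' exactly the transpose of stage 2.
#'
#' @param A n x n binary symmetric adjacency.
#' @param idx nonempty vector of sampled node indices.
#' @return a `stage_adjacencies` list with `A1`, `A2`, `A3`, `A4`.
#' @export
stage_adjacencies <- function(A, idx) {
  n <- nrow(A)
  idx <- as.integer(idx)
  if (length(idx) == 0L || any(idx < 1L | idx > n))
    stop("`idx` must be a nonempty subset of node indices", call. = FALSE)
  in_idx <- logical(n); in_idx[idx] <- TRUE
  A2 <- A * (outer(!in_idx, in_idx) * 1)
  A3 <- matrix(0, n, n)
  A3[idx, idx] <- A[idx, idx]
  structure(list(A1 = A, A2 = A2, A3 = A3, A4 = t(A2)),
            class = "stage_adjacencies")
}

#' Initialize the weights of one collapse block
#'
#' Four independent equivariant layers, one per stage. Stage 1 uses the
#' message attention gate and no normalization; stages 2-4 use normalization
#' and no gate.
#'
#' @param d feature width.
#' @return a `collapse_weights` list of four `egcl_weights`.
#' @export
collapse_init <- function(d) {
  structure(list(
    s1 = egcl_init(d, use_attention = TRUE, normalize = FALSE),
    s2 = egcl_init(d, use_attention = FALSE, normalize = TRUE),
    s3 = egcl_init(d, use_attention = FALSE, normalize = TRUE),
    s4 = egcl_init(d, use_attention = FALSE, normalize = TRUE)
  ), class = "collapse_weights")
}

.collapse_block <- function(state, stages, weights, coord_stages = "all") {
  upd <- if (identical(coord_stages, "stage1")) c(TRUE, FALSE, FALSE, FALSE)
         else rep(TRUE, 4L)
  H_in <- state$H
  st <- state
  st <- .egcl_forward(st, stages$A1, weights$s1, update_x = upd[1L])
  st <- .egcl_forward(st, stages$A2, weights$s2, update_x = upd[2L])
  st <- .egcl_forward(st, stages$A3, weights$s3, update_x = upd[3L])
  st <- .egcl_forward(st, stages$A4, weights$s4, update_x = upd[4L])
  st$H <- ad_add(H_in, st$H)  # block-level residual
  st
}

#' Run one collapse/unpooling block
#'
#' Applies the four stage layers in order and adds the block input to the
#' scalar output as a residual. Coordinates are updated at every stage.
#'
#' @param state list with `H` (n x d) and `X` (n x 3).
#' @param stages a `stage_adjacencies`.
#' @param weights a `collapse_weights`.
#' @param coord_stages `"all"` (default) updates coordinates at every stage;
#'   `"stage1"` freezes them after the first stage.
#' @return list with updated `H` and `X`.
#' @export
collapse_block <- function(state, stages, weights, coord_stages = "all") {
  out <- .collapse_block(list(H = ad_const(as_mat(state$H)),
                              X = ad_const(as_mat(state$X))), stages, weights,
                         coord_stages = coord_stages)
  list(H = ad_value(out$H), X = ad_value(out$X))
}

#' One-block indirect reachability diagnostic
#'
#' Boolean reachability of information flow through one block: nodes keep
#' their own state at every stage (skip connections), so flow is the
#' composition `(I + A1)(I + A2)(I + A3)(I + A4) > 0`. Reports whether a
#' residue can reach distant residues through sampled mediators within a
#' single block.
#'
#' @param A n x n adjacency.
#' @param idx sampled node indices.
#' @return n x n logical matrix; `[u, v]` is `TRUE` when u's information can
#'   reach v within one block.
#' @export
indirect_reach_check <- function(A, idx) {
  st <- stage_adjacencies(A, idx)
  n <- nrow(A)
  I <- diag(n)
  M <- (I + st$A1) %*% (I + st$A2) %*% (I + st$A3) %*% (I + st$A4)
  M > 0
}
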