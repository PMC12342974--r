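# The full predictor: input projection, one pooling selection, a stack of
# collapse blocks, and a two-class MLP head.

#' Model configuration
#'
#' Defaults are the production settings of the predictor: 14 A contact
#' threshold, 15 A pseudo-position scale, 8 collapse blocks of width 128,
#' 30% sampling, hop-1 clusters, Adam at 5e-4 with 1e-5 L2 regularization,
#' 60 epochs, and plateau learning-rate decay (factor 0.6, patience 10,
#' floor 1e-6) on validation AUPRC.
#'
#' @param n_layers number of collapse blocks.
#' @param hidden_dim node feature width after input projection.
#' @param sampling_ratio pooling ratio in (0, 1].
#' @param hop soft-cluster radius in edges.
#' @param distance_threshold contact cutoff (Angstrom).
#' @param pef_scale pseudo-position normalizing length (Angstrom).
#' @param learning_rate,weight_decay Adam step size and L2 strength.
#' @param epochs training epochs.
#' @param lr_decay_factor,lr_patience,lr_min plateau scheduler parameters.
#' @param seed master seed for initialization, splits and shuffling.
#' @param recompute_selection recompute the pooling selection from the
#'   current state at every block instead of once from the input state.
#' @param regate_per_block re-apply score gating to the sampled rows at the
#'   start of every block instead of once when the selection is formed.
#' @param coord_stages `"all"` updates coordinates at every collapse stage;
#'   `"stage1"` freezes them after the first stage of each block.
#' @return a `model_config` list.
#' @export
model_config <- function(n_layers = 8L, hidden_dim = 128L,
                         sampling_ratio = 0.30, hop = 1L,
                         distance_threshold = 14, pef_scale = 15,
                         learning_rate = 5e-4, weight_decay = 1e-5,
                         epochs = 60L, lr_decay_factor = 0.6,
                         lr_patience = 10L, lr_min = 1e-6, seed = 1L,
                         recompute_selection = FALSE,
                         regate_per_block = FALSE,
                         coord_stages = c("all", "stage1")) {
  cfg <- list(n_layers = as.integer(n_layers), hidden_dim = as.integer(hidden_dim),
              sampling_ratio = sampling_ratio, hop = as.integer(hop),
              distance_threshold = distance_threshold, pef_scale = pef_scale,
              learning_rate = learning_rate, weight_decay = weight_decay,
              epochs = as.integer(epochs), lr_decay_factor = lr_decay_factor,
              lr_patience = as.integer(lr_patience), lr_min = lr_min,
              seed = as.integer(seed),
              recompute_selection = isTRUE(recompute_selection),
              regate_per_block = isTRUE(regate_per_block),
              coord_stages = match.arg(coord_stages))
  num <- cfg[c("n_layers", "hidden_dim", "sampling_ratio", "hop",
               "distance_threshold", "pef_scale", "learning_rate",
               "weight_decay", "epochs", "lr_decay_factor", "lr_patience",
               "lr_min")]
  if (any(vapply(num, function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop("all configuration values must be positive", call. = FALSE)
  if (cfg$sampling_ratio > 1) stop("`sampling_ratio` must lie in (0, 1]", call. = FALSE)
  structure(cfg, class = "model_config")
}

#' Initialize model weights
#'
#' @param config a [model_config()].
#' @param d_in input feature width (62, 320 or 1342 for the standard groups).
#' @return a `model_weights` list (input projection, pooling weights, one
#'   `collapse_weights` per block, MLP head).
#' @export
model_init <- function(config, d_in) {
  d <- config$hidden_dim
  with_seed(config$seed, function() {
    structure(list(
      proj = list(W = matrix(stats::rnorm(d_in * d, sd = sqrt(1 / d_in)), d_in, d),
                  b = matrix(0, 1L, d)),
      asap = asap_init(d),
      blocks = lapply(seq_len(config$n_layers), function(b) collapse_init(d)),
      head = mlp_init(d, d, 2L)
    ), class = "model_weights")
  })
}

# Tape-level forward shared by inference and training.
# Returns list(logits, idx, phi, state).
.model_forward <- function(graph, w, config) {
  H_raw <- graph$H
  if (ncol(H_raw) != nrow(ad_value(w$proj$W)))
    stop(sprintf("graph feature width %d does not match model input width %d",
                 ncol(H_raw), nrow(ad_value(w$proj$W))), call. = FALSE)
  A <- graph$A
  n <- nrow(A)
  Hn <- ad_add(ad_matmul(ad_const(H_raw), w$proj$W), w$proj$b)
  Xn <- ad_const(graph$X)
  phi <- .asap_scores(Hn, Xn, A, w$asap, config$hop)
  phi_v <- ad_value(phi)[, 1L]
  idx <- top_fraction_idx(phi_v, config$sampling_ratio)
  gate <- function(Hc, phi_node, sel) {
    mask <- matrix(0, n, 1L); mask[sel, 1L] <- 1
    ad_add(ad_mul(Hc, ad_const(1 - mask)),
           ad_mul(ad_mul(Hc, phi_node), ad_const(mask)))
  }
  # score-gate the sampled rows once, before the first block (default)
  stages <- stage_adjacencies(A, idx)
  state <- list(H = gate(Hn, phi, idx), X = Xn)
  for (b in seq_len(config$n_layers)) {
    if (b > 1L && config$recompute_selection) {
      phi <- .asap_scores(state$H, state$X, A, w$asap, config$hop)
      phi_v <- ad_value(phi)[, 1L]
      idx <- top_fraction_idx(phi_v, config$sampling_ratio)
      stages <- stage_adjacencies(A, idx)
      state$H <- gate(state$H, phi, idx)
    } else if (b > 1L && config$regate_per_block) {
      state$H <- gate(state$H, phi, idx)
    }
    state <- .collapse_block(state, stages, w$blocks[[b]],
                             coord_stages = config$coord_stages)
  }
  logits <- mlp_forward(w$head, state$H)
  list(logits = logits, idx = idx, phi = phi_v, state = state)
}

#' Run the predictor on one protein graph
#'
#' Projects the input features, forms one pooling selection, runs the stack
#' of collapse blocks and the MLP head, and softmaxes the two-class output.
#'
#' @param graph a [protein_graph()] whose feature width matches the model.
#' @param weights a `model_weights` (or a fitted `sc_model`).
#' @param config a [model_config()]; taken from the model when omitted.
#' @return tibble with one row per residue: `residue`, `prob` (positive-class
#'   probability), `call` (binary at 0.5), `sampled` (pooling membership).
#' @export
model_forward <- function(graph, weights, config = NULL) {
  if (inherits(weights, "sc_model")) {
    config <- config %||% weights$config
    weights <- weights$weights
  }
  stopifnot(!is.null(config))
  out <- .model_forward(graph, weights, config)
  p <- ad_value(ad_softmax_rows(out$logits))[, 2L]
  n <- length(p)
  tibble::tibble(residue = seq_len(n), prob = p,
                 call = as.integer(p >= 0.5),
                 sampled = seq_len(n) %in% out$idx)
}
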