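# Training loop, plateau learning-rate schedule and protein-level
# cross-validation.

#' Plateau learning-rate scheduler
#'
#' Multiplies the learning rate by `factor` whenever the monitored metric has
#' failed to increase for `patience` consecutive epochs, never dropping below
#' `lr_min`. `scheduler_step()` consumes one epoch's metric and returns the
#' updated state, whose `lr` applies to the next epoch.
#'
#' @param lr0 initial learning rate.
#' @param factor multiplicative decay.
#' @param patience epochs without improvement before decay.
#' @param lr_min learning-rate floor.
#' @return scheduler state list (`lr`, `best`, `bad`).
#' @export
scheduler_init <- function(lr0, factor = 0.6, patience = 10L, lr_min = 1e-6) {
  list(lr = lr0, factor = factor, patience = as.integer(patience),
       lr_min = lr_min, best = -Inf, bad = 0L)
}

#' @rdname scheduler_init
#' @param state scheduler state.
#' @param metric the epoch's monitored value (higher is better).
#' @export
scheduler_step <- function(state, metric) {
  if (is.na(metric) || metric > state$best) {
    state$best <- if (is.na(metric)) state$best else metric
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$lr_min)
      state$bad <- 0L
    }
  }
  state
}

build_graphs <- function(dataset, config, group) {
  lapply(dataset, function(p) {
    protein_graph(p$coords, p$features, threshold = config$distance_threshold,
                  group = group, labels = p$labels)
  })
}

collect_scores <- function(graphs, weights, config) {
  scores <- numeric(0); labels <- integer(0)
  for (g in graphs) {
    pr <- model_forward(g, weights, config)
    scores <- c(scores, pr$prob)
    labels <- c(labels, g$labels)
  }
  list(scores = scores, labels = labels)
}

#' Train the predictor
#'
#' One Adam step per protein per epoch (each protein is its own graph batch),
#' cross-entropy loss, L2 regularization, and plateau learning-rate decay
#' monitored on validation AUPRC. When no validation set is supplied, 10% of
#' the proteins (at least one, chosen by seeded id-keyed assignment) are held
#' out as the monitor split; pass `val_dataset` explicitly to train on every
#' protein.
#'
#' @param dataset list of proteins (each with `coords`, `features`, `labels`),
#'   e.g. from [generate_dataset()].
#' @param config a [model_config()].
#' @param feature_group which feature group to train on (see
#'   [feature_group()]).
#' @param val_dataset optional validation proteins for the plateau monitor.
#' @return an `sc_model`: `weights`, `config`, `feature_group`, `log`
#'   (per-epoch tibble: `epoch`, `loss`, `val_auprc`, `lr`), `val_ids`.
#' @export
train <- function(dataset, config = model_config(),
                  feature_group = "handcrafted", val_dataset = NULL) {
  if (length(dataset) == 0L) stop("`dataset` must be nonempty", call. = FALSE)
  ids <- vapply(dataset, function(p) p$id %||% "", character(1))
  if (any(ids == "")) ids <- paste0("p", seq_along(dataset))
  if (is.null(val_dataset)) {
    if (length(dataset) >= 2L) {
      n_val <- max(1L, round(0.1 * length(dataset)))
      val_ids <- with_seed(config$seed, function() {
        sample(sort(ids), n_val)
      })
      val_dataset <- dataset[ids %in% val_ids]
      dataset <- dataset[!ids %in% val_ids]
      ids <- ids[!ids %in% val_ids]
    } else {
      val_dataset <- dataset  # degenerate single-protein case
    }
  }
  val_ids <- vapply(val_dataset, function(p) p$id %||% "", character(1))
  graphs <- build_graphs(dataset, config, feature_group)
  val_graphs <- build_graphs(val_dataset, config, feature_group)
  d_in <- ncol(graphs[[1L]]$H)
  params <- unclass(model_init(config, d_in))
  opt <- adam_init(params)
  sched <- scheduler_init(config$learning_rate, config$lr_decay_factor,
                          config$lr_patience, config$lr_min)
  log <- vector("list", config$epochs)
  order_seeds <- with_seed(config$seed, function() {
    sample.int(.Machine$integer.max - 1L, config$epochs)
  })
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(order_seeds[epoch], function() sample(seq_along(graphs)))
    losses <- numeric(length(ord))
    for (j in seq_along(ord)) {
      g <- graphs[[ord[j]]]
      wn <- wrap_params(params)
      out <- .model_forward(g, wn, config)
      loss <- ad_softmax_ce(out$logits, g$labels)
      ad_backward(loss)
      res <- adam_step(params, grads_of(wn), opt, lr = sched$lr,
                       weight_decay = config$weight_decay)
      params <- res$params; opt <- res$state
      losses[j] <- loss$val[1L, 1L]
    }
    val <- collect_scores(val_graphs, params, config)
    val_auprc <- tryCatch(auprc(val$labels, val$scores),
                          error = function(e) NA_real_)
    log[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                   val_auprc = val_auprc, lr = sched$lr)
    sched <- scheduler_step(sched, val_auprc)
  }
  structure(list(weights = structure(params, class = "model_weights"),
                 config = config, feature_group = feature_group,
                 d_in = d_in, log = dplyr::bind_rows(log),
                 train_ids = ids, val_ids = val_ids),
            class = "sc_model")
}

#' @export
#' @method print sc_model
print.sc_model <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(paste0("<sc_model: %s features (%d-d), %d blocks x %d hidden;\n",
                     "  %d epochs, final loss %.4f, val AUPRC %.3f>\n"),
              x$feature_group, x$d_in, x$config$n_layers, x$config$hidden_dim,
              nrow(x$log), last$loss, last$val_auprc))
  invisible(x)
}

#' Predict interaction-site probabilities for proteins
#'
#' @param object a fitted `sc_model`.
#' @param newdata list of proteins or a single [protein_graph()].
#' @param ... unused.
#' @return tibble with `protein`, `residue`, `prob`, `call`, `sampled`.
#' @export
predict.sc_model <- function(object, newdata, ...) {
  if (inherits(newdata, "protein_graph")) {
    return(dplyr::mutate(model_forward(newdata, object), protein = "graph",
                         .before = 1L))
  }
  graphs <- build_graphs(newdata, object$config, object$feature_group)
  ids <- vapply(newdata, function(p) p$id %||% "", character(1))
  dplyr::bind_rows(lapply(seq_along(graphs), function(i) {
    dplyr::mutate(model_forward(graphs[[i]], object), protein = ids[i],
                  .before = 1L)
  }))
}

#' Protein-level k-fold assignment
#'
#' Folds are keyed to sorted protein ids under the seed, so shuffling the
#' input order never changes the assignment.
#'
#' @param ids character vector of protein ids.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold label per input id.
#' @export
fold_assignment <- function(ids, k, seed) {
  u <- sort(unique(ids))
  if (length(u) < k) stop("fewer proteins than folds", call. = FALSE)
  perm <- with_seed(seed, function() sample(u))
  fold_of <- rep(seq_len(k), length.out = length(u))
  names(fold_of) <- perm
  unname(fold_of[ids])
}

#' k-fold cross-validation at the protein level
#'
#' Splits proteins (never residues) into `k` folds, trains on `k - 1` and
#' evaluates on the held-out fold.
#'
#' @inheritParams train
#' @param k number of folds (default 5).
#' @return an `sc_cv`: tibble of per-fold metrics with a `summary` attribute
#'   (column means) and `folds` attribute (assignment).
#' @export
cross_validate <- function(dataset, config = model_config(), k = 5L,
                           feature_group = "handcrafted") {
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  ids <- vapply(dataset, function(p) p$id, character(1))
  folds <- fold_assignment(ids, k, config$seed)
  rows <- lapply(seq_len(k), function(f) {
    fit <- train(dataset[folds != f], config, feature_group,
                 val_dataset = dataset[folds == f])
    test_graphs <- build_graphs(dataset[folds == f], config, feature_group)
    sc <- collect_scores(test_graphs, fit$weights, config)
    dplyr::mutate(evaluate(sc$labels, sc$scores), fold = f, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sc_cv", class(out)),
            summary = dplyr::summarise(out, dplyr::across(
              c("ACC", "Precision", "Recall", "F1", "MCC", "AUROC", "AUPRC"),
              mean)),
            folds = stats::setNames(folds, ids))
}
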