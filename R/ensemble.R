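# Feature-group bagging ensemble with a logistic-regression meta-model.
#
# Six base models are trained independently, one per feature group: the
# 62-column handcrafted block, the four 320-column language-model chunks, and
# the full 1342-column concatenation. Their positive-class probabilities are
# stacked residue-wise into a width-6 input for a logistic meta-model.

#' Feature groups of the ensemble, in stacking order
#' @return character vector of the six group names.
#' @export
ensemble_groups <- function() c("handcrafted", paste0("chunk", 1:4), "all")

#' Train the six feature-group base models
#'
#' Each group is trained independently with its own deterministic seed
#' (derived from `config$seed`), so identical inputs give identical
#' checkpoints.
#'
#' @inheritParams train
#' @return named list of six `sc_model` fits, in [ensemble_groups()] order.
#' @export
train_base_models <- function(dataset, config = model_config(),
                              val_dataset = NULL) {
  groups <- ensemble_groups()
  fits <- lapply(seq_along(groups), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    train(dataset, cfg, feature_group = groups[i], val_dataset = val_dataset)
  })
  names(fits) <- groups
  fits
}

#' Stack base-model predictions residue-wise
#'
#' Column `j` is base model `j`'s positive-class probability, in the fixed
#' order handcrafted, chunk1..chunk4, all.
#'
#' @param models named list of six `sc_model` fits (see
#'   [train_base_models()]).
#' @param dataset list of proteins to predict on.
#' @param binarize feed hard 0/1 calls instead of probabilities.
#' @return list with `x` (n_residues x 6 matrix), `labels` (or `NULL`),
#'   `protein` (id per residue).
#' @export
stack_predictions <- function(models, dataset, binarize = FALSE) {
  groups <- ensemble_groups()
  stopifnot(all(groups %in% names(models)))
  cols <- lapply(groups, function(g) {
    pr <- predict(models[[g]], dataset)
    if (binarize) as.numeric(pr$call) else pr$prob
  })
  nres <- lengths(cols)
  if (length(unique(nres)) != 1L)
    stop("base models disagree on residue count", call. = FALSE)
  x <- do.call(cbind, cols)
  colnames(x) <- groups
  labels <- unlist(lapply(dataset, function(p) p$labels), use.names = FALSE)
  protein <- unlist(lapply(dataset, function(p) rep(p$id, nrow(p$coords))),
                    use.names = FALSE)
  list(x = x, labels = if (length(labels)) labels else NULL, protein = protein)
}

#' Fit the logistic-regression meta-model
#'
#' L2-regularized logistic regression (ridge penalty, fixed small strength
#' and convergence threshold) on the width-6 stacked inputs.
#'
#' @param x n x 6 matrix of stacked base-model outputs (or the list returned
#'   by [stack_predictions()]).
#' @param labels 0/1 vector (ignored when `x` carries labels).
#' @param lambda ridge penalty (default 1e-4).
#' @return an `sc_meta`: `w` (length-6 weights), `b` (intercept).
#' @export
fit_meta <- function(x, labels = NULL, lambda = 1e-4) {
  if (is.list(x) && !is.null(x$x)) {
    labels <- labels %||% x$labels
    x <- x$x
  }
  x <- as_mat(x)
  if (length(unique(labels)) < 2L)
    stop("meta-model labels contain a single class", call. = FALSE)
  fit <- glmnet::glmnet(x, factor(labels, levels = c(0, 1)),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE, thresh = 1e-12)
  cf <- as.numeric(stats::coef(fit))
  structure(list(w = cf[-1L], b = cf[1L], lambda = lambda,
                 groups = colnames(x) %||% ensemble_groups()),
            class = "sc_meta")
}

#' @export
#' @method print sc_meta
print.sc_meta <- function(x, ...) {
  cat("<sc_meta: logistic stacker>\n")
  print(round(stats::setNames(c(x$b, x$w), c("(intercept)", x$groups)), 4))
  invisible(x)
}

#' Predict with the meta-model
#'
#' Closed-form `sigmoid(w . x + b)` on each stacked row; binary call at 0.5.
#'
#' @param meta an `sc_meta`.
#' @param x n x 6 stacked matrix or a [stack_predictions()] result.
#' @return tibble with `prob` and `call` per residue.
#' @export
predict_meta <- function(meta, x) {
  if (is.list(x) && !is.null(x$x)) x <- x$x
  x <- as_mat(x)
  if (ncol(x) != length(meta$w))
    stop(sprintf("stacked input has %d columns; meta-model expects %d",
                 ncol(x), length(meta$w)), call. = FALSE)
  z <- drop(x %*% meta$w) + meta$b
  p <- 1 / (1 + exp(-z))
  tibble::tibble(prob = p, call = as.integer(p >= 0.5))
}

#' Train the full ensemble
#'
#' Trains the six base models, stacks their predictions on the training
#' proteins and fits the logistic meta-model. With `oof_folds` set, the
#' stacked inputs are out-of-fold: each protein's base-model predictions come
#' from fits that never saw it, avoiding stacking leakage.
#'
#' @inheritParams train
#' @param oof_folds optional integer; use out-of-fold stacking with this many
#'   protein-level folds.
#' @return an `sc_ensemble`: `base` (six `sc_model`s), `meta` (`sc_meta`).
#' @export
ensemble_train <- function(dataset, config = model_config(),
                           val_dataset = NULL, oof_folds = NULL) {
  base <- train_base_models(dataset, config, val_dataset)
  if (is.null(oof_folds)) {
    stacked <- stack_predictions(base, dataset)
  } else {
    ids <- vapply(dataset, function(p) p$id, character(1))
    folds <- fold_assignment(ids, oof_folds, config$seed)
    parts <- lapply(seq_len(oof_folds), function(f) {
      fold_fits <- train_base_models(dataset[folds != f], config,
                                     val_dataset = dataset[folds == f])
      stack_predictions(fold_fits, dataset[folds == f])
    })
    stacked <- list(x = do.call(rbind, lapply(parts, `[[`, "x")),
                    labels = unlist(lapply(parts, `[[`, "labels")),
                    protein = unlist(lapply(parts, `[[`, "protein")))
  }
  structure(list(base = base, meta = fit_meta(stacked), config = config),
            class = "sc_ensemble")
}

#' Predict with the full ensemble
#'
#' @param object an `sc_ensemble`.
#' @param newdata list of proteins.
#' @param ... unused.
#' @return tibble with `protein`, `residue`, `prob`, `call`.
#' @export
predict.sc_ensemble <- function(object, newdata, ...) {
  stacked <- stack_predictions(object$base, newdata)
  pr <- predict_meta(object$meta, stacked)
  residue <- unlist(lapply(newdata, function(p) seq_len(nrow(p$coords))),
                    use.names = FALSE)
  dplyr::mutate(pr, protein = stacked$protein, residue = residue,
                .before = 1L)
}
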