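# Plain-text (JSON) checkpoints for fitted models.

mat_to_rec <- function(x) {
  if (is.list(x)) lapply(x, mat_to_rec)
  else if (is.numeric(x)) list(dim = dim(as_mat(x)), v = as.numeric(as_mat(x)))
  else x
}

rec_to_mat <- function(x) {
  if (is.list(x) && !is.null(x$dim) && !is.null(x$v))
    matrix(unlist(x$v), x$dim[[1]], x$dim[[2]])
  else if (is.list(x)) lapply(x, rec_to_mat)
  else x
}

#' Write a fitted model to a JSON checkpoint
#'
#' One self-describing text file: a header with the configuration, feature
#' group and input width, the training log, and every weight matrix with its
#' dimensions at full precision.
#'
#' @param model an `sc_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sc_model"))
  payload <- list(
    header = list(format = "sitecollapse-checkpoint", version = 1L,
                  feature_group = model$feature_group, d_in = model$d_in,
                  config = unclass(model$config)),
    log = as.list(model$log),
    weights = mat_to_rec(unclass(model$weights)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint written by [write_checkpoint()]
#' @param path checkpoint file.
#' @return an `sc_model`.
#' @export
read_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$header$format, "sitecollapse-checkpoint"))
    stop("not a sitecollapse checkpoint: ", path, call. = FALSE)
  cfg <- do.call(model_config, p$header$config)
  w <- rec_to_mat(p$weights)
  # restore layer flags to plain logicals
  log <- tibble::as_tibble(lapply(p$log, function(col)
    unlist(lapply(col, function(x) if (is.null(x)) NA_real_ else x))))
  structure(list(weights = structure(w, class = "model_weights"),
                 config = cfg, feature_group = p$header$feature_group,
                 d_in = p$header$d_in, log = log,
                 train_ids = character(0), val_ids = character(0)),
            class = "sc_model")
}
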