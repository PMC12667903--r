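# Checkpoint and database persistence. Model weights go in an RDS file with
# a JSON sidecar carrying the configuration and training log; embedding
# databases are written as a TSV id index next to a plain-text matrix so
# they stay portable and diffable.

#' Save / load a trained encoder
#'
#' `save_model()` writes `path` (RDS, weights + config) and, when jsonlite
#' is available, `<path>.json` with the configuration and training log for
#' inspection. `load_model()` restores the encoder.
#'
#' @param model a `cp_encoder`.
#' @param path checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cp_encoder"))
  saveRDS(model, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(config = unclass(model$config),
                 training_log = model$training_log)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cp_encoder"))
  model
}

#' Write / read an embedding database as TSV
#'
#' One row per structure: `id`, `model_tag`, then the embedding columns.
#'
#' @param db an `embedding_db`.
#' @param path TSV file path.
#' @return `write_embedding_db()` returns `path` invisibly;
#'   `read_embedding_db()` the restored database.
#' @export
write_embedding_db <- function(db, path) {
  stopifnot(inherits(db, "embedding_db"))
  out <- data.frame(id = db$ids, model_tag = db$model_tag,
                    db$matrix, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_db
#' @export
read_embedding_db <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(mat) <- tab$id
  structure(list(ids = tab$id, matrix = unname(mat),
                 model_tag = tab$model_tag[1], config_hash = ""),
            class = "embedding_db")
}
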