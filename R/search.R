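# Embedding database, cosine search, and the dual-model circular-permutation
# discovery pipeline: a CP-sensitive encoder (trained without synCP
# augmentation) and a CP-invariant encoder (trained with it) score every
# pair; pairs the sensitive model misses but the invariant model matches are
# CP candidates, which the duplicate-and-align TM aligner then verifies.

#' Pipeline configuration for CP discovery
#'
#' Defaults follow the dual-model filter: candidate pairs either score
#' below `baseline_max` under the CP-sensitive model while scoring above
#' `invariant_min` under the CP-invariant model (`mode = "threshold"`), or
#' show a score difference of at least `diff_min` (`mode = "difference"`).
#' `retrieval_cutoff` is the cosine above which a database hit counts as a
#' recovered homolog; `tm_cp_min` is the fold cutoff used at verification.
#'
#' @param mode `"threshold"` or `"difference"`.
#' @param baseline_max,invariant_min,diff_min,retrieval_cutoff,tm_cp_min
#'   numeric cutoffs (see description).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("threshold", "difference"),
                            baseline_max = 0.6, invariant_min = 0.9,
                            diff_min = 0.7, retrieval_cutoff = 0.8,
                            tm_cp_min = 0.5) {
  structure(list(mode = match.arg(mode), baseline_max = baseline_max,
                 invariant_min = invariant_min, diff_min = diff_min,
                 retrieval_cutoff = retrieval_cutoff,
                 tm_cp_min = tm_cp_min),
            class = "pipeline_config")
}

#' Embed a set of structures into a searchable database
#'
#' Structures that fail graph preconditions (e.g. too short) are skipped
#' with a warning rather than aborting the batch.
#'
#' @param traces list of [ca_trace] objects.
#' @param model a `cp_encoder`.
#' @param model_tag short tag recorded with the database (e.g.
#'   `"baseline"` or `"invariant"`).
#' @return An `embedding_db`: list with `ids`, `matrix` (N x embed_dim),
#'   `model_tag`, `config_hash`.
#' @export
embed_database <- function(traces, model, model_tag = "model") {
  stopifnot(inherits(model, "cp_encoder"), length(traces) >= 1L)
  rows <- list(); ids <- character(0)
  for (tr in traces) {
    emb <- tryCatch(encode(build_graph(tr), model), error = function(e) {
      warning("skipping ", tr$id, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(emb)) {
      rows[[length(rows) + 1L]] <- as.numeric(emb)
      ids <- c(ids, tr$id)
    }
  }
  if (length(rows) == 0L) stop("no structure could be embedded")
  if (anyDuplicated(ids)) stop("duplicate structure ids")
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  structure(list(ids = ids, matrix = mat, model_tag = model_tag,
                 config_hash = paste(unlist(model$config), collapse = "|")),
            class = "embedding_db")
}

row_normalize <- function(M) M / sqrt(rowSums(M^2))

#' Cosine search against an embedding database
#'
#' @param query numeric embedding vector (from [encode()]).
#' @param db an [embed_database()] result with matching width.
#' @param top_k number of hits to return.
#' @return data.frame with `id`, `cosine`, `rank`, sorted by descending
#'   cosine (ties broken by id).
#' @export
cosine_search <- function(query, db, top_k = 10L) {
  stopifnot(inherits(db, "embedding_db"))
  q <- as.numeric(query)
  if (length(q) != ncol(db$matrix)) stop("embedding dimension mismatch")
  cos <- as.numeric(row_normalize(db$matrix) %*% (q / sqrt(sum(q^2))))
  ord <- order(-cos, db$ids)
  k <- min(top_k, length(ord))
  data.frame(id = db$ids[ord[seq_len(k)]], cosine = cos[ord[seq_len(k)]],
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Discover circularly permuted pairs with the dual-model filter
#'
#' Embeds every structure under both encoders, computes all-vs-all cosine
#' similarities, filters unordered pairs through the configured candidate
#' rule, and verifies each candidate with [delta_cp()]. The verified set
#' contains the candidates with `is_cp = TRUE` (CP-aware TM above the fold
#' cutoff and a strictly positive improvement from allowing the wrap).
#'
#' @param traces list of [ca_trace] objects (>= 2).
#' @param model_baseline CP-sensitive encoder (trained without synCP
#'   augmentation).
#' @param model_invariant CP-invariant encoder (trained with it).
#' @param cfg a [pipeline_config()].
#' @param verify run the alignment verification stage (switch it off to
#'   audit the candidate filter alone; verification columns stay `NA`).
#' @return A `cp_discovery`: list with `candidates` (data.frame of all
#'   filtered pairs with scores and verification columns), `verified`
#'   (the `is_cp` subset) and `config`.
#' @export
discover_cp <- function(traces, model_baseline, model_invariant,
                        cfg = pipeline_config(), verify = TRUE) {
  stopifnot(length(traces) >= 2L)
  if (model_baseline$config$embed_dim != model_invariant$config$embed_dim)
    stop("the two models must share an embedding convention")
  db_b <- embed_database(traces, model_baseline, "baseline")
  db_i <- embed_database(traces, model_invariant, "invariant")
  shared <- intersect(db_b$ids, db_i$ids)
  Sb <- tcrossprod(row_normalize(db_b$matrix[shared, , drop = FALSE]))
  Si <- tcrossprod(row_normalize(db_i$matrix[shared, , drop = FALSE]))
  N <- length(shared)
  ut <- which(upper.tri(Sb), arr.ind = TRUE)
  tab <- data.frame(id_a = shared[ut[, 1L]], id_b = shared[ut[, 2L]],
                    score_baseline = Sb[ut], score_invariant = Si[ut],
                    stringsAsFactors = FALSE)
  tab$diff <- tab$score_invariant - tab$score_baseline
  keep <- if (cfg$mode == "threshold") {
    tab$score_baseline < cfg$baseline_max &
      tab$score_invariant > cfg$invariant_min
  } else {
    tab$diff >= cfg$diff_min
  }
  cand <- tab[keep, , drop = FALSE]
  by_id <- stats::setNames(traces[match(shared,
                                        vapply(traces, `[[`, "", "id"))],
                           shared)
  cand$tm <- cand$tm_cp <- cand$delta_cp <- rep(NA_real_, nrow(cand))
  cand$is_cp <- rep(NA, nrow(cand))
  if (verify && nrow(cand) > 0L) {
    for (r in seq_len(nrow(cand))) {
      v <- delta_cp(by_id[[cand$id_a[r]]], by_id[[cand$id_b[r]]],
                    tm_cp_min = cfg$tm_cp_min)
      cand$tm[r] <- v$tm; cand$tm_cp[r] <- v$tm_cp
      cand$delta_cp[r] <- v$delta_cp; cand$is_cp[r] <- v$is_cp
    }
  }
  rownames(cand) <- NULL
  structure(list(candidates = cand,
                 verified = cand[which(cand$is_cp), , drop = FALSE],
                 config = cfg, n_structures = N),
            class = "cp_discovery")
}

#' @export
print.cp_discovery <- function(x, ...) {
  cat(sprintf(
    "<cp_discovery> %d structures, %d candidate pairs, %d verified CPs\n",
    x$n_structures, nrow(x$candidates), nrow(x$verified)))
  invisible(x)
}

#' Node-level cosine similarity map
#'
#' Cosine similarity between every per-node embedding of one structure and
#' every per-node embedding of another (or itself), exposing which
#' residue-level substructures the encoder regards as equivalent.
#'
#' @param trace_a,trace_b [ca_trace] objects.
#' @param model a `cp_encoder`.
#' @return n_a x n_b matrix of cosines in `[-1, 1]`; unit diagonal when
#'   `trace_a` and `trace_b` are the same structure.
#' @export
node_similarity_map <- function(trace_a, trace_b, model) {
  Ha <- row_normalize(node_embeddings(build_graph(trace_a), model))
  Hb <- row_normalize(node_embeddings(build_graph(trace_b), model))
  tcrossprod(Ha, Hb)
}

#' PCA projection of an embedding database
#'
#' Centered principal-component scores, components ordered by decreasing
#' variance, sign fixed so each component's largest-magnitude loading is
#' positive.
#'
#' @param db an [embed_database()] result with more rows than components.
#' @param n_components number of components.
#' @return N x n_components score matrix with rownames from `db$ids`.
#' @export
project_pca <- function(db, n_components = 2L) {
  stopifnot(inherits(db, "embedding_db"))
  N <- nrow(db$matrix)
  if (N <= n_components)
    stop("need more structures than components")
  pc <- stats::prcomp(db$matrix, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- db$ids
  scores
}
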