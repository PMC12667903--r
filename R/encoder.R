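# E(3)-invariant graph encoder.
#
# Message passing uses node features and squared inter-node distances only
# (no raw coordinates reach the invariant channels), so per-node and pooled
# embeddings are exactly invariant to rigid motions by construction.
# Invariance to *circular permutation* is not architectural: it is learned,
# when requested, by replacing each sampled training structure with a random
# synCP of itself (the positional encoding and terminal flags then differ
# while the geometry does not).
#
# No deep-learning runtime is involved: forward, backward (manual
# backpropagation) and the Adam optimizer are plain R matrix algebra.

FEATURE_WIDTH <- 67L  # density (1) + terminal flags (2) + encoding (64)

#' Encoder configuration
#'
#' @param n_layers number of message-passing layers.
#' @param hidden_dim per-node hidden width.
#' @param embed_dim output embedding width.
#' @param temperature supervised-contrastive temperature (> 0).
#' @param lr Adam learning rate.
#' @param batch_families families sampled per iteration.
#' @param members_per_family structures sampled per family per iteration.
#' @param epochs training epochs.
#' @param seed RNG seed controlling initialization and sampling.
#' @param syncp_augment if `TRUE`, every sampled training structure is
#'   replaced by a random synCP of itself (cut offset uniform on
#'   `0..n-1`, including the identity), the mechanism that makes the
#'   learned embedding circular-permutation invariant.
#' @return A `model_config` list.
#' @export
model_config <- function(n_layers = 3L, hidden_dim = 32L, embed_dim = 32L,
                         temperature = 0.05, lr = 3e-3,
                         batch_families = 6L, members_per_family = 4L,
                         epochs = 100L, seed = 1L, syncp_augment = TRUE) {
  cfg <- list(n_layers = as.integer(n_layers),
              hidden_dim = as.integer(hidden_dim),
              embed_dim = as.integer(embed_dim),
              temperature = temperature, lr = lr,
              batch_families = as.integer(batch_families),
              members_per_family = as.integer(members_per_family),
              epochs = as.integer(epochs), seed = as.integer(seed),
              syncp_augment = isTRUE(syncp_augment))
  stopifnot(cfg$n_layers >= 1, cfg$hidden_dim >= 1, cfg$embed_dim >= 1,
            cfg$temperature > 0, cfg$lr > 0, cfg$batch_families >= 2,
            cfg$members_per_family >= 2, cfg$epochs >= 1)
  class(cfg) <- "model_config"
  cfg
}

#' Initialize an encoder with random weights
#'
#' Useful on its own for testing architectural (as opposed to learned)
#' invariances; [train()] starts from this.
#'
#' @param config a [model_config()].
#' @return A `cp_encoder`: list with `params`, `config`, `training_log`.
#' @export
init_model <- function(config = model_config()) {
  H <- config$hidden_dim; E <- config$embed_dim
  with_seed(config$seed, {
    rw <- function(nin, nout) matrix(rnorm(nin * nout, sd = 1 / sqrt(nin)),
                                     nin, nout)
    params <- list(W_in = rw(FEATURE_WIDTH, H), b_in = numeric(H))
    for (l in seq_len(config$n_layers)) {
      params[[paste0("Wm_", l)]] <- rw(2L * H + 1L, H)
      params[[paste0("bm_", l)]] <- numeric(H)
      params[[paste0("Wu_", l)]] <- rw(2L * H, H)
      params[[paste0("bu_", l)]] <- numeric(H)
    }
    params$W_out <- rw(H, E)
    params$b_out <- numeric(E)
    structure(list(params = params, config = config, training_log = NULL),
              class = "cp_encoder")
  })
}

# ---- graph batching ---------------------------------------------------------

# directed edge arrays for one graph
graph_tensors <- function(graph) {
  i <- graph$edges[, 1L]; j <- graph$edges[, 2L]
  src <- c(i, j); dst <- c(j, i)
  list(X = graph$features, src = src, dst = dst,
       e = c(graph$edge_d2, graph$edge_d2) / 100,  # cutoff^2 normalization
       n = graph$n_nodes)
}

batch_tensors <- function(tensors) {
  ns <- vapply(tensors, function(t) t$n, 0L)
  off <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(tensors, function(t) t$X))
  src <- unlist(mapply(function(t, o) t$src + o, tensors, off,
                       SIMPLIFY = FALSE))
  dst <- unlist(mapply(function(t, o) t$dst + o, tensors, off,
                       SIMPLIFY = FALSE))
  e <- unlist(lapply(tensors, function(t) t$e))
  N <- sum(ns)
  gid <- rep(seq_along(tensors), ns)
  list(X = X, src = src, dst = dst, e = e, N = N, gid = gid, ns = ns,
       deg = tabulate(dst, N))
}

addb <- function(M, b) M + rep(b, each = nrow(M))

scatter_sum <- function(N, M, group) {
  out <- matrix(0, N, ncol(M))
  rs <- rowsum(M, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# forward pass over a batched graph; returns pooled embeddings (one row per
# graph), final per-node features, and (optionally) the caches backprop needs
gnn_forward <- function(params, bt, n_layers, keep_cache = FALSE) {
  dg <- pmax(bt$deg, 1L)
  H <- tanh(addb(bt$X %*% params$W_in, params$b_in))
  cache <- if (keep_cache) list(H0 = H) else NULL
  for (l in seq_len(n_layers)) {
    Z <- cbind(H[bt$src, , drop = FALSE], H[bt$dst, , drop = FALSE], bt$e)
    M <- tanh(addb(Z %*% params[[paste0("Wm_", l)]],
                   params[[paste0("bm_", l)]]))
    A <- scatter_sum(bt$N, M, bt$dst) / dg
    U <- tanh(addb(cbind(H, A) %*% params[[paste0("Wu_", l)]],
                   params[[paste0("bu_", l)]]))
    if (keep_cache) cache[[paste0("l", l)]] <- list(H_in = H, M = M,
                                                    A = A, U = U)
    H <- H + U
  }
  G <- rowsum(H, bt$gid) / bt$ns
  Zout <- addb(G %*% params$W_out, params$b_out)
  list(Z = Zout, nodes = H, G = G, cache = cache)
}

# backpropagate dL/dZout; returns gradient list matching params
gnn_backward <- function(params, bt, fw, dZ, n_layers) {
  dg <- pmax(bt$deg, 1L)
  grads <- list(W_out = crossprod(fw$G, dZ), b_out = colSums(dZ))
  dG <- dZ %*% t(params$W_out)
  dH <- (dG / bt$ns)[bt$gid, , drop = FALSE]
  Hd <- ncol(dH)
  for (l in rev(seq_len(n_layers))) {
    cl <- fw$cache[[paste0("l", l)]]
    dU <- dH * (1 - cl$U^2)
    CA <- cbind(cl$H_in, cl$A)
    grads[[paste0("Wu_", l)]] <- crossprod(CA, dU)
    grads[[paste0("bu_", l)]] <- colSums(dU)
    dCA <- dU %*% t(params[[paste0("Wu_", l)]])
    dHin <- dH + dCA[, seq_len(Hd), drop = FALSE]
    dA <- dCA[, Hd + seq_len(Hd), drop = FALSE]
    dM <- (dA / dg)[bt$dst, , drop = FALSE]
    dA1 <- dM * (1 - cl$M^2)
    Z <- cbind(cl$H_in[bt$src, , drop = FALSE],
               cl$H_in[bt$dst, , drop = FALSE], bt$e)
    grads[[paste0("Wm_", l)]] <- crossprod(Z, dA1)
    grads[[paste0("bm_", l)]] <- colSums(dA1)
    dZe <- dA1 %*% t(params[[paste0("Wm_", l)]])
    dHin <- dHin + scatter_sum(bt$N, dZe[, seq_len(Hd), drop = FALSE],
                               bt$src)
    dHin <- dHin + scatter_sum(bt$N, dZe[, Hd + seq_len(Hd), drop = FALSE],
                               bt$dst)
    dH <- dHin
  }
  dpre <- dH * (1 - fw$cache$H0^2)
  grads$W_in <- crossprod(bt$X, dpre)
  grads$b_in <- colSums(dpre)
  grads
}

# ---- public encoding --------------------------------------------------------

#' Embed a structure
#'
#' Runs the graph through the encoder and mean-pools the final node features
#' into a fixed-width embedding. The output is exactly invariant to rigid
#' motions of the input coordinates and to the storage order of the edge
#' list; embeddings are compared downstream by cosine similarity.
#'
#' @param graph a [build_graph()] result.
#' @param model a `cp_encoder` (trained or freshly initialized).
#' @return Numeric embedding vector of length `embed_dim`, with attribute
#'   `structure_id`.
#' @export
encode <- function(graph, model) {
  stopifnot(inherits(graph, "protein_graph"), inherits(model, "cp_encoder"))
  if (ncol(graph$features) != FEATURE_WIDTH)
    stop("feature width mismatch: expected ", FEATURE_WIDTH)
  fw <- gnn_forward(model$params, batch_tensors(list(graph_tensors(graph))),
                    model$config$n_layers)
  structure(as.numeric(fw$Z[1L, ]), structure_id = graph$id)
}

#' Per-node embeddings
#'
#' Final-layer node feature vectors before pooling; the linear output map
#' applied to their mean reproduces [encode()].
#'
#' @inheritParams encode
#' @return n x hidden_dim matrix.
#' @export
node_embeddings <- function(graph, model) {
  stopifnot(inherits(graph, "protein_graph"), inherits(model, "cp_encoder"))
  fw <- gnn_forward(model$params, batch_tensors(list(graph_tensors(graph))),
                    model$config$n_layers)
  fw$nodes
}

# ---- supervised contrastive loss -------------------------------------------

#' Supervised contrastive loss
#'
#' L2-normalizes the embeddings and, for each anchor that has at least one
#' positive (another sample with the same label), averages
#' `-log( exp(z_i . z_p / t) / sum_{a != i} exp(z_i . z_a / t) )` over its
#' positives; the loss is the mean over such anchors. Anchors without a
#' positive are excluded; if no anchor has one, this errors.
#'
#' @param embeddings numeric matrix, one row per sample.
#' @param labels vector of class labels, one per row.
#' @param temperature positive scaling temperature.
#' @return Nonnegative scalar loss.
#' @export
supcon_loss <- function(embeddings, labels, temperature = 0.1) {
  supcon_loss_grad(embeddings, labels, temperature, want_grad = FALSE)$loss
}

supcon_loss_grad <- function(embeddings, labels, temperature = 0.1,
                             want_grad = TRUE) {
  Z <- as.matrix(embeddings)
  B <- nrow(Z)
  stopifnot(B >= 2L, length(labels) == B, temperature > 0)
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm == 0)) stop("zero embedding vector")
  Zn <- Z / nrm
  logits <- tcrossprod(Zn) / temperature
  diag(logits) <- -Inf
  pos <- outer(labels, labels, "==")
  diag(pos) <- FALSE
  npos <- rowSums(pos)
  anchors <- npos > 0L
  if (!any(anchors)) stop("no anchor has a positive")
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  per_anchor <- rowSums(ifelse(pos, lse - logits, 0))[anchors] /
    npos[anchors]
  loss <- mean(per_anchor)
  if (!want_grad) return(list(loss = loss))
  nA <- sum(anchors)
  q <- exp(logits - lse)  # softmax over non-self, zero on the diagonal
  G <- matrix(0, B, B)
  G[anchors, ] <- (q[anchors, , drop = FALSE] -
                     pos[anchors, , drop = FALSE] / npos[anchors]) /
    (temperature * nA)
  dZn <- (G + t(G)) %*% Zn
  dot <- rowSums(dZn * Zn)
  grad <- (dZn - Zn * dot) / nrm
  list(loss = loss, grad = grad)
}

# ---- training ---------------------------------------------------------------

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the encoder with synCP-augmented supervised contrastive learning
#'
#' Each iteration samples `batch_families` families and
#' `members_per_family` structures per family; when `syncp_augment` is on,
#' every sampled structure is replaced by a random synCP of itself before
#' its graph features are rebuilt. Positives are all same-family samples in
#' the batch. If validation traces are supplied, retrieval sensitivity
#' (mean over the hierarchy levels that have true positives, all-vs-all
#' within the validation set) is evaluated periodically and the
#' best-scoring weights are returned; otherwise the final weights are.
#' Deterministic for a fixed `config$seed`.
#'
#' @param traces list of labeled [ca_trace] objects; at least two families
#'   with at least two members each.
#' @param config a [model_config()].
#' @param val_traces optional list of labeled traces for model selection.
#' @param eval_every epochs between validation evaluations.
#' @param verbose print per-epoch progress.
#' @return A trained `cp_encoder`; `training_log` is a data.frame with
#'   per-epoch mean loss and (if evaluated) validation sensitivity.
#' @export
train <- function(traces, config = model_config(), val_traces = NULL,
                  eval_every = 5L, verbose = FALSE) {
  labels <- vapply(traces, function(t) t$labels %||% NA_character_, "")
  if (anyNA(labels)) stop("all training traces need family labels")
  fam_idx <- split(seq_along(traces), labels)
  if (length(fam_idx) < 2L || !all(lengths(fam_idx) >= 2L))
    stop("training needs >= 2 families with >= 2 members each")
  model <- init_model(config)
  params <- model$params
  graphs <- lapply(traces, build_graph)
  val_bt <- NULL
  if (!is.null(val_traces)) {
    val_graphs <- lapply(val_traces, build_graph)
    val_bt <- batch_tensors(lapply(val_graphs, graph_tensors))
    val_labels <- vapply(val_traces, function(t) t$labels, "")
  }
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n_fam <- length(fam_idx)
  bf <- min(config$batch_families, n_fam)
  log_epoch <- numeric(0); log_loss <- numeric(0); log_val <- numeric(0)
  best_val <- -Inf; best_params <- params
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      fam_order <- sample.int(n_fam)
      losses <- numeric(0)
      for (g0 in seq(1L, n_fam, by = bf)) {
        fams <- fam_order[g0:min(g0 + bf - 1L, n_fam)]
        if (length(fams) < 2L) next
        sel <- unlist(lapply(fams, function(fi) {
          idx <- fam_idx[[fi]]
          sample(idx, config$members_per_family,
                 replace = length(idx) < config$members_per_family)
        }))
        gs <- lapply(sel, function(i) {
          g <- graphs[[i]]
          if (config$syncp_augment)
            g <- syncp_graph(g, sample.int(g$n_nodes, 1L) - 1L)
          g
        })
        bt <- batch_tensors(lapply(gs, graph_tensors))
        fw <- gnn_forward(params, bt, config$n_layers, keep_cache = TRUE)
        sl <- supcon_loss_grad(fw$Z, labels[sel], config$temperature)
        grads <- gnn_backward(params, bt, fw, sl$grad, config$n_layers)
        upd <- adam_step(params, grads, state, config$lr)
        params <- upd$params; state <- upd$state
        losses <- c(losses, sl$loss)
      }
      log_epoch <- c(log_epoch, ep)
      log_loss <- c(log_loss, mean(losses))
      vs <- NA_real_
      if (!is.null(val_bt) && (ep %% eval_every == 0L ||
                               ep == config$epochs)) {
        emb <- gnn_forward(params, val_bt, config$n_layers)$Z
        vs <- mean_retrieval_sensitivity(emb, val_labels)
        if (vs >= best_val) { best_val <- vs; best_params <- params }
      }
      log_val <- c(log_val, vs)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  val %s\n", ep,
                    mean(losses), ifelse(is.na(vs), "-", sprintf("%.3f", vs))))
    }
  })
  model$params <- if (is.null(val_bt)) params else best_params
  model$training_log <- data.frame(epoch = log_epoch, loss = log_loss,
                                   val_sensitivity = log_val)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean retrieval sensitivity over queries and over the hierarchy levels
# that have true positives, from an embedding matrix + label vector
mean_retrieval_sensitivity <- function(emb, labels,
                                       levels = c("family", "superfamily",
                                                  "fold")) {
  Zn <- emb / sqrt(rowSums(emb^2))
  S <- tcrossprod(Zn)
  vals <- c()
  for (i in seq_len(nrow(S))) {
    ord <- order(-S[i, -i])
    ranked <- labels[-i][ord]
    for (lv in levels) {
      s <- retrieval_sensitivity(labels[i], ranked, lv)
      if (!is.na(s)) vals <- c(vals, s)
    }
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Retrieval sensitivity up to the first false positive
#'
#' For one query with hierarchy label `"class.fold.superfamily.family"` and
#' a ranked list of target labels (query excluded), counts the fraction of
#' the query's true positives that rank above its first false positive.
#' True positives at family level share the full label; at superfamily
#' level they share the superfamily but not the family; at fold level the
#' fold but not the superfamily. False positives are targets from a
#' different fold; targets in between (e.g. same fold, wrong family, at
#' family level) are ignored.
#'
#' @param query_label sccs-style label of the query.
#' @param ranked_target_labels character vector of target labels in rank
#'   order (best first).
#' @param level `"family"`, `"superfamily"` or `"fold"`.
#' @return Fraction in `[0, 1]`, or `NA` if the level has no true
#'   positives for this query.
#' @examples
#' retrieval_sensitivity("a.1.1.1",
#'                       c("a.1.1.1", "a.1.1.1", "b.2.1.1", "a.1.1.1"),
#'                       "family")  # 2/3
#' @export
retrieval_sensitivity <- function(query_label, ranked_target_labels,
                                  level = c("family", "superfamily",
                                            "fold")) {
  level <- match.arg(level)
  qp <- strsplit(query_label, ".", fixed = TRUE)[[1L]]
  tp <- strsplit(ranked_target_labels, ".", fixed = TRUE)
  same_to <- function(parts, depth) {
    length(parts) >= depth && all(parts[seq_len(depth)] == qp[seq_len(depth)])
  }
  is_tp <- vapply(tp, function(p) switch(
    level,
    family = same_to(p, 4L),
    superfamily = same_to(p, 3L) && !same_to(p, 4L),
    fold = same_to(p, 2L) && !same_to(p, 3L)), NA)
  is_fp <- !vapply(tp, same_to, NA, depth = 2L)
  n_tp <- sum(is_tp)
  if (n_tp == 0L) return(NA_real_)
  first_fp <- which(is_fp)[1L]
  if (is.na(first_fp)) return(1)
  sum(is_tp[seq_len(first_fp - 1L)]) / n_tp
}
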