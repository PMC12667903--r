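# TM-score structural alignment with a circular-permutation mode.
#
# The aligner is a simplified TM-align-style heuristic: seeds from gapless
# threading and fragment superpositions, each refined by iterating
# {superpose on the mapped set -> TM-style score matrix -> global DP with a
# -0.6 gap-open penalty (no extension, free end gaps) -> new mapping}. The
# CP mode duplicates the query so the alignment can wrap around the cut
# point, then re-aligns in the best cyclic frame. All scores here come from
# this one aligner on both arms (plain and CP), so the difference statistic
# delta_cp retains its meaning even though absolute scores may deviate from
# the reference TM-align binary.

#' Kabsch superposition
#'
#' Least-squares proper rotation (reflections corrected by the determinant
#' sign) and translation superposing `X` onto `Y` (`X %*% rotation +
#' translation` approximates `Y`). Collinear point sets make the rotation
#' ill-determined and are flagged with a warning.
#'
#' @param X,Y m x 3 coordinate matrices in correspondence, m >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation`
#'   (length-3), `rmsd` (Angstrom) and `degenerate` flag.
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  res <- cpp_kabsch(X, Y)
  if (isTRUE(res$degenerate))
    warning("collinear point set: rotation is ill-determined")
  res$translation <- as.numeric(res$translation)
  res
}

#' TM-score length scale d0
#'
#' `d0 = max(0.5, 1.24 (L - 15)^(1/3) - 1.8)`; lengths of 15 or fewer use
#' the 0.5 Angstrom floor directly.
#'
#' @param L_norm normalization length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L_norm) cpp_d0(as.integer(L_norm))

#' TM-score of a fixed residue mapping
#'
#' `TM = (1/L_norm) * sum over mapped pairs of 1 / (1 + (d_i/d0)^2)`, with
#' distances taken after the TM-score-optimal superposition (found by
#' iterative subset refinement over the mapped pairs).
#'
#' @param X,Y full coordinate matrices of the two structures.
#' @param mapping two-column integer matrix of (query, target) indices.
#' @param L_norm normalization length.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(X, Y, mapping, L_norm) {
  mapping <- as.matrix(mapping)
  if (nrow(mapping) == 0L) stop("empty mapping")
  cpp_tm_score(as.matrix(X), as.matrix(Y),
               as.integer(mapping[, 1L]), as.integer(mapping[, 2L]),
               as.integer(L_norm))
}

# core on raw coordinates; the seed search runs in both directions (the DP
# is not direction-symmetric) and the mapping with the better min-normalized
# TM wins, which makes the score symmetric in its arguments
align_core <- function(XA, XB, gap_open = -0.6, max_iter = 30L) {
  fwd <- cpp_align(XA, XB, gap_open, max_iter)
  rev <- cpp_align(XB, XA, gap_open, max_iter)
  best <- NULL
  for (res in list(list(qi = fwd$qi, tj = fwd$tj),
                   list(qi = rev$tj, tj = rev$qi))) {
    tm_q <- cpp_tm_score(XA, XB, res$qi, res$tj, nrow(XA))
    tm_t <- cpp_tm_score(XA, XB, res$qi, res$tj, nrow(XB))
    cur <- list(qi = res$qi, tj = res$tj, tm_query = tm_q,
                tm_target = tm_t, tm_min = min(tm_q, tm_t))
    if (is.null(best) || cur$tm_min > best$tm_min) best <- cur
  }
  kb <- cpp_kabsch(XA[best$qi, , drop = FALSE],
                   XB[best$tj, , drop = FALSE])
  list(mapping = cbind(best$qi, best$tj), rotation = kb$rotation,
       translation = as.numeric(kb$translation), rmsd = kb$rmsd,
       tm_query = best$tm_query, tm_target = best$tm_target,
       tm_min = best$tm_min)
}

#' Structural alignment of two Calpha traces
#'
#' Sequence-order-dependent alignment (see the file header for the
#' heuristic). `tm_query` is normalized by the query length, `tm_target`
#' by the target length; `tm_min`, their minimum, is the global-similarity
#' score used throughout (a value above 0.5 indicates a shared fold, below
#' 0.17 randomness).
#'
#' @param A,B [ca_trace] objects with at least 20 residues.
#' @param gap_open DP gap-open penalty.
#' @param max_iter refinement iteration cap per seed.
#' @return A `cp_alignment`: `mapping` (two-column index matrix, strictly
#'   increasing in both columns), `rotation`, `translation`, `rmsd`,
#'   `tm_query`, `tm_target`, `tm_min`, `cp_mode`, `cp_offset`.
#' @export
align <- function(A, B, gap_open = -0.6, max_iter = 30L) {
  stopifnot(inherits(A, "ca_trace"), inherits(B, "ca_trace"))
  if (trace_length(A) < 20L || trace_length(B) < 20L)
    stop("alignment needs traces of at least 20 residues")
  out <- align_core(A$coords, B$coords, gap_open, max_iter)
  out$cp_mode <- FALSE
  out$cp_offset <- NULL
  out$id_a <- A$id; out$id_b <- B$id
  class(out) <- "cp_alignment"
  out
}

#' @export
print.cp_alignment <- function(x, ...) {
  cat(sprintf(
    "<cp_alignment>%s %s vs %s: %d pairs, rmsd %.2f, TM %.3f/%.3f (min %.3f)%s\n",
    if (x$cp_mode) " [cp]" else "", x$id_a %||% "A", x$id_b %||% "B",
    nrow(x$mapping), x$rmsd, x$tm_query, x$tm_target, x$tm_min,
    if (!is.null(x$cp_offset)) sprintf(", cut %d", x$cp_offset) else ""))
  invisible(x)
}

# most frequent value
stat_mode <- function(x) as.integer(names(which.max(table(x))))

#' Circular-permutation-aware alignment (duplicate and align)
#'
#' Aligns the doubled query `concat(A, A)` against the target so the
#' alignment can wrap around the termini, infers candidate cut offsets from
#' the wrapped mapping, and re-runs the plain aligner on the cyclically
#' shifted query in each candidate frame (offset 0, i.e. the plain
#' alignment, is always among the candidates, so the CP score can never
#' fall below the plain score). TM scores are normalized by the original
#' chain lengths; each original query residue is mapped at most once.
#'
#' @inheritParams align
#' @return A `cp_alignment` with `cp_mode = TRUE`; `cp_offset` is the
#'   inferred cut position (mapping indices refer to the query cyclically
#'   shifted by `cp_offset`).
#' @export
align_cp <- function(A, B, gap_open = -0.6, max_iter = 30L) {
  stopifnot(inherits(A, "ca_trace"), inherits(B, "ca_trace"))
  n <- trace_length(A)
  if (n < 20L || trace_length(B) < 20L)
    stop("alignment needs traces of at least 20 residues")
  XA2 <- rbind(A$coords, A$coords)
  wrap <- cpp_align(XA2, B$coords, gap_open, max_iter)
  oi <- (wrap$qi - 1L) %% n          # original 0-based query indices
  cand <- unique(c(0L,
                   oi[which.min(wrap$tj)],
                   stat_mode((oi - (wrap$tj - 1L)) %% n)))
  best <- NULL
  for (k in cand) {
    ord <- if (k == 0L) seq_len(n) else c((k + 1L):n, seq_len(k))
    res <- align_core(A$coords[ord, , drop = FALSE], B$coords,
                      gap_open, max_iter)
    if (is.null(best) || res$tm_min > best$tm_min) {
      best <- res
      best$cp_offset <- as.integer(k)
    }
  }
  best$cp_mode <- TRUE
  best$id_a <- A$id; best$id_b <- B$id
  class(best) <- "cp_alignment"
  best
}

#' Circular-permutation verdict for a pair
#'
#' Computes the plain and CP-aware minimum-normalized TM scores and their
#' difference. A pair is called circularly permuted when the CP-aware score
#' clears the fold-similarity cutoff (`tm_cp > 0.5`) and allowing the wrap
#' strictly improved the alignment (`delta_cp > 0`).
#'
#' @inheritParams align
#' @param tm_cp_min fold-similarity cutoff on the CP-aware score.
#' @return A `cp_verdict`: list with `tm`, `tm_cp`, `delta_cp`, `is_cp`,
#'   and the underlying `alignment` / `alignment_cp` objects.
#' @export
delta_cp <- function(A, B, tm_cp_min = 0.5, gap_open = -0.6,
                     max_iter = 30L) {
  plain <- align(A, B, gap_open, max_iter)
  cp <- align_cp(A, B, gap_open, max_iter)
  tm <- plain$tm_min
  tm_cp <- max(cp$tm_min, tm)  # CP search space includes the plain one
  delta <- tm_cp - tm
  structure(list(tm = tm, tm_cp = tm_cp, delta_cp = delta,
                 is_cp = (tm_cp > tm_cp_min) && (delta > 0),
                 alignment = plain, alignment_cp = cp),
            class = "cp_verdict")
}

#' @export
print.cp_verdict <- function(x, ...) {
  cat(sprintf("<cp_verdict> TM %.3f, TM-cp %.3f, delta %.3f -> %s\n",
              x$tm, x$tm_cp, x$delta_cp,
              if (x$is_cp) "circular permutation" else "no CP"))
  invisible(x)
}
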