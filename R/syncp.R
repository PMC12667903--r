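#' Synthetic circular permutation (synCP)
#'
#' A k-synCP cyclically reorders the Calpha sequence of a structure without
#' moving any atom: the chain is conceptually circularized and re-cut after
#' residue k, giving the new order \eqn{p_{k+1},\dots,p_n,p_1,\dots,p_k}.
#' `k = 0` is the identity; offsets are canonicalized to `[0, n)` so that
#' applying `syncp(. , k)` followed by `syncp(. , n - k)` restores the
#' original order exactly.
#'
#' @param trace a [ca_trace].
#' @param k integer cut offset, `0 <= k < n`.
#' @return A `syncp_record`: list with `parent_id`, `k` and `child`
#'   (a [ca_trace] whose coordinates are the cyclic reordering).
#' @examples
#' tr <- ca_trace(cbind(3.8 * (0:9), 0, 0), id = "toy")
#' rec <- syncp(tr, 3)
#' rec$child$coords[1, ]  # == tr$coords[4, ]
#' @export
syncp <- function(trace, k) {
  stopifnot(inherits(trace, "ca_trace"))
  n <- trace_length(trace)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L || k >= n)
    stop("k must satisfy 0 <= k < n (n = ", n, ")")
  ord <- if (k == 0L) seq_len(n) else c((k + 1L):n, seq_len(k))
  child <- ca_trace(trace$coords[ord, , drop = FALSE],
                    id = sprintf("%s_cp%d", trace$id, k),
                    labels = trace$labels)
  structure(list(parent_id = trace$id, k = k, child = child),
            class = "syncp_record")
}

#' Enumerate every synCP of a structure
#'
#' A chain of length n has exactly n circular permutations (including the
#' identity at `k = 0`); this returns all of them.
#'
#' @param trace a [ca_trace].
#' @return List of n `syncp_record`s, in order `k = 0, ..., n - 1`.
#' @export
enumerate_syncps <- function(trace) {
  stopifnot(inherits(trace, "ca_trace"))
  lapply(0:(trace_length(trace) - 1L), function(k) syncp(trace, k))
}
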