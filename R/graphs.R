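#' Contact-graph representation of a Calpha trace
#'
#' Nodes are residues; an undirected edge joins two residues whose Calpha
#' atoms lie within 10 Angstrom of each other (inclusive). Each node carries
#' a 67-dimensional feature vector: normalized local density (1), terminal
#' indicator (2) and a sinusoidal positional encoding (64). Edges and
#' density depend only on inter-atom distances, so they are invariant to
#' rigid motions; the terminal flags and positional encoding depend only on
#' residue order, so a synCP changes exactly those.
#'
#' @param trace a [ca_trace] with at least 20 residues (positional encoding
#'   and density are degenerate on very short chains).
#' @param cutoff contact distance cutoff in Angstrom.
#' @return A `protein_graph`: list with `n_nodes`, `edges` (two-column
#'   matrix of index pairs, `i < j`), `edge_d2` (squared distance per edge),
#'   `coords` and `features` (n x 67 matrix, columns density, N-flag,
#'   C-flag, 64 encoding dims).
#' @export
build_graph <- function(trace, cutoff = 10) {
  stopifnot(inherits(trace, "ca_trace"))
  n <- trace_length(trace)
  if (n < 20L) stop("graph construction needs at least 20 residues, got ", n)
  d <- as.matrix(dist(trace$coords))
  adj <- d <= cutoff
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- unname(idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE])
  feats <- cbind(local_density(trace$coords, cutoff),
                 terminal_flags(n),
                 positional_encoding(n))
  colnames(feats) <- NULL
  structure(list(n_nodes = n, edges = edges,
                 edge_d2 = d[edges]^2,
                 coords = trace$coords, features = feats,
                 id = trace$id),
            class = "protein_graph")
}

#' Normalized local density
#'
#' Counts, for each residue, the Calpha atoms within the cutoff
#' (self included) and normalizes by the maximum count over the chain, so
#' values lie in (0, 1] and the densest residue scores 1.
#'
#' @param coords n x 3 coordinate matrix.
#' @param cutoff neighborhood radius, Angstrom.
#' @return Numeric vector of length n.
#' @examples
#' local_density(cbind(c(0, 6, 12), 0, 0))  # 2/3, 1, 2/3
#' @export
local_density <- function(coords, cutoff = 10) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 1L) return(1)
  d <- as.matrix(dist(coords))
  alpha <- rowSums(d <= cutoff)  # diagonal is 0 <= cutoff: self included
  unname(alpha / max(alpha))
}

#' Terminal indicator features
#'
#' Row 1 is `(1, 0)` (N-terminus), row n is `(0, 1)` (C-terminus), all
#' interior rows `(0, 0)`.
#'
#' @param n chain length (>= 2).
#' @return n x 2 binary matrix.
#' @export
terminal_flags <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("terminal flags need n >= 2")
  tau <- matrix(0, n, 2L)
  tau[1L, 1L] <- 1
  tau[n, 2L] <- 1
  tau
}

#' Sinusoidal positional encoding
#'
#' Standard transformer-style encoding with base 10000 and interleaved
#' sine/cosine columns; positions are 0-based in the current residue order,
#' so a synCP child receives freshly computed encodings.
#'
#' @param n number of positions.
#' @param d encoding width (even).
#' @return n x d matrix with entries in `[-1, 1]`;
#'   `s[i+1, 2j+1] = sin(i / 10000^(2j/d))`,
#'   `s[i+1, 2j+2] = cos(i / 10000^(2j/d))`.
#' @export
positional_encoding <- function(n, d = 64L) {
  n <- as.integer(n); d <- as.integer(d)
  if (d %% 2L != 0L) stop("encoding width d must be even")
  stopifnot(n >= 1L)
  pos <- 0:(n - 1L)
  j <- 0:(d / 2L - 1L)
  freq <- 1 / 10000^(2 * j / d)
  arg <- outer(pos, freq)
  s <- matrix(0, n, d)
  s[, 2L * j + 1L] <- sin(arg)
  s[, 2L * j + 2L] <- cos(arg)
  s
}

# Fast graph for a synCP child: coordinates are unchanged, so edges and
# density only need relabeling by the cyclic index map; terminal flags and
# positional encoding are recomputed for the new order.
syncp_graph <- function(graph, k) {
  n <- graph$n_nodes
  k <- as.integer(k)
  if (k == 0L) return(graph)
  ord <- c((k + 1L):n, seq_len(k))      # child position -> parent index
  pos <- integer(n); pos[ord] <- seq_len(n)  # parent index -> child position
  e <- cbind(pos[graph$edges[, 1L]], pos[graph$edges[, 2L]])
  flip <- e[, 1L] > e[, 2L]
  e[flip, ] <- e[flip, c(2L, 1L), drop = FALSE]
  o <- order(e[, 1L], e[, 2L])
  feats <- graph$features
  feats <- cbind(feats[ord, 1L], terminal_flags(n), positional_encoding(n))
  colnames(feats) <- NULL
  structure(list(n_nodes = n, edges = e[o, , drop = FALSE],
                 edge_d2 = graph$edge_d2[o],
                 coords = graph$coords[ord, , drop = FALSE],
                 features = feats,
                 id = sprintf("%s_cp%d", graph$id, k)),
            class = "protein_graph")
}
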