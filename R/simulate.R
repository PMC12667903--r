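# Synthetic backbone generator: labeled families of rigid Calpha traces built
# from idealized secondary-structure elements, planted circular permutants and
# cross-family decoys. Stands in for curated domain databases so the full
# train/search/verify pipeline runs offline.

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# rotation taking the unit z axis onto unit vector d (Rodrigues)
rot_align_z <- function(d) {
  d <- d / sqrt(sum(d^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * d[3] - z[3] * d[2],
         z[3] * d[1] - z[1] * d[3],
         z[1] * d[2] - z[2] * d[1])
  c_ <- sum(z * d)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))  # antiparallel
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3L,
               byrow = TRUE)
  diag(3L) + vx + vx %*% vx / (1 + c_)
}

# idealized elements, built along the local +z axis starting at the origin
ideal_helix <- function(m, rise = 1.5, turn = 100 * pi / 180, radius = 2.3) {
  i <- 0:(m - 1L)
  cbind(radius * cos(turn * i) - radius, radius * sin(turn * i), rise * i)
}

ideal_strand <- function(m, rise = 3.4, zig = 0.9) {
  i <- 0:(m - 1L)
  cbind(zig * (i %% 2), 0, rise * i)
}

# loop: smooth random walk with 3.8 A steps starting at origin, initial
# direction +z, direction re-drawn with persistence
loop_walk <- function(m, step = 3.8, persist = 0.6) {
  p <- matrix(0, m, 3L)
  d <- c(0, 0, 1)
  for (i in 2:m) {
    d <- persist * d + (1 - persist) * rnorm(3L)
    d <- d / sqrt(sum(d^2))
    p[i, ] <- p[i - 1L, ] + step * d
  }
  p
}

# pick an extension direction for the next element, biased to keep the chain
# endpoint within r_max of the origin (compactness)
pick_direction <- function(p_start, extent, r_max) {
  for (try in 1:30) {
    d <- rnorm(3L); d <- d / sqrt(sum(d^2))
    if (sqrt(sum((p_start + d * extent)^2)) <= r_max) return(d)
  }
  d <- -p_start + rnorm(3L) * 2
  d / sqrt(sum(d^2))
}

# append an element (local coords, along +z, origin start) to a growing chain
append_element <- function(chain, elem, r_max) {
  p_last <- chain[nrow(chain), ]
  extent <- max(elem[, 3]) + 3.8
  d <- pick_direction(p_last, extent, r_max)
  rot <- rot_align_z(d) %*% rot_z(runif(1, 0, 2 * pi))
  placed <- elem %*% t(rot)
  placed <- sweep(placed, 2L, p_last + 3.8 * d - placed[1L, ], "+")
  rbind(chain, placed)
}

rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3L, byrow = TRUE)
}

# family template: helices and strands joined by loops, trimmed to `length`
build_template <- function(length) {
  r_max <- 4.2 * length^(1 / 3)
  chain <- matrix(0, 1L, 3L)
  repeat {
    if (runif(1) < 0.55) {
      elem <- ideal_helix(sample(8:16, 1L))
    } else {
      elem <- ideal_strand(sample(5:10, 1L))
    }
    chain <- append_element(chain, elem, r_max)
    if (nrow(chain) >= length + 1L) break
    chain <- append_element(chain, loop_walk(sample(3:6, 1L)), r_max)
    if (nrow(chain) >= length + 1L) break
  }
  chain[2:(length + 1L), , drop = FALSE]  # drop the origin anchor
}

#' Generate a synthetic structure family
#'
#' Builds one rigid family template by concatenating idealized
#' secondary-structure elements (helix: 1.5 Angstrom rise, 100 degree turn,
#' 2.3 Angstrom radius; strand: 3.4 Angstrom rise zig-zag) joined by
#' random-walk loops, then emits members as the template plus i.i.d. Gaussian
#' coordinate noise and a random rigid motion. All members carry the same
#' family label. Generation is deterministic for a fixed seed, and the first
#' `k` members are identical whether `n_members = k` or larger (so extra
#' members can serve as a held-out set).
#'
#' @param n_members number of members (>= 1).
#' @param length chain length (>= 20 residues).
#' @param noise_sd coordinate noise standard deviation, Angstrom.
#' @param seed integer seed.
#' @param label family label attached to every member
#'   (sccs-style `"class.fold.superfamily.family"`).
#' @return List of [ca_trace] members.
#' @examples
#' fam <- make_synthetic_family(3, 40, 0.2, seed = 1)
#' sapply(fam, trace_length)
#' @export
make_synthetic_family <- function(n_members, length, noise_sd, seed,
                                  label = sprintf("s.%d.1.1", seed)) {
  stopifnot(n_members >= 1, length >= 20, noise_sd >= 0)
  with_seed(seed, {
    template <- build_template(length)
    lapply(seq_len(n_members), function(i) {
      coords <- template + matrix(rnorm(3L * length, sd = noise_sd),
                                  ncol = 3L)
      coords <- coords %*% t(random_rotation())
      coords <- sweep(coords, 2L, runif(3L, -20, 20), "+")
      ca_trace(coords, id = sprintf("%s_m%d", gsub("\\.", "-", label), i),
               labels = label)
    })
  })
}

#' Generate a planted circular-permutation benchmark
#'
#' For each of `n_families` synthetic families, the last member is replaced
#' by a synCP of the first member (cut offset drawn from
#' `[length/4, 3 length/4]`) plus coordinate noise, and the pair is recorded
#' as a planted circular permutant. Cross-family pairs are recorded as
#' non-CP decoys. Families carry distinct fold-level labels.
#'
#' @param n_families,members,length,noise_sd,seed generation parameters;
#'   all sizes positive, `length >= 20`.
#' @return A `syn_cp_benchmark`: list with `traces` (list of [ca_trace]),
#'   `cp_pairs` (data.frame `id_a`, `id_b`, `k`), `decoy_pairs`
#'   (data.frame `id_a`, `id_b`) and `seed`.
#' @export
make_cp_benchmark <- function(n_families, members, length, noise_sd, seed) {
  stopifnot(n_families >= 1, members >= 2, length >= 20, noise_sd >= 0)
  fams <- lapply(seq_len(n_families), function(j) {
    make_synthetic_family(members, length, noise_sd, seed = seed * 1000L + j,
                          label = sprintf("a.%d.1.1", j))
  })
  cp <- with_seed(seed * 1000L, {
    lapply(seq_len(n_families), function(j) {
      src <- fams[[j]][[1L]]
      k <- sample(floor(length / 4):floor(3 * length / 4), 1L)
      ord <- c((k + 1L):length, seq_len(k))
      coords <- src$coords[ord, , drop = FALSE] +
        matrix(rnorm(3L * length, sd = noise_sd), ncol = 3L)
      child <- ca_trace(coords, id = sprintf("a-%d-1-1_cp", j),
                        labels = src$labels)
      list(child = child, k = k, src_id = src$id)
    })
  })
  traces <- list()
  for (j in seq_len(n_families)) {
    fam <- fams[[j]]
    fam[[members]] <- cp[[j]]$child  # replaces the last member
    traces <- c(traces, fam)
  }
  cp_pairs <- data.frame(
    id_a = vapply(cp, function(x) x$src_id, ""),
    id_b = vapply(cp, function(x) x$child$id, ""),
    k = vapply(cp, function(x) as.integer(x$k), 0L),
    stringsAsFactors = FALSE)
  decoy_pairs <- if (n_families >= 2) {
    data.frame(
      id_a = vapply(seq_len(n_families - 1L),
                    function(j) fams[[j]][[2L]]$id, ""),
      id_b = vapply(seq_len(n_families - 1L),
                    function(j) fams[[j + 1L]][[2L]]$id, ""),
      stringsAsFactors = FALSE)
  } else data.frame(id_a = character(), id_b = character())
  structure(list(traces = traces, cp_pairs = cp_pairs,
                 decoy_pairs = decoy_pairs, seed = seed),
            class = "syn_cp_benchmark")
}

#' Synthetic trace with an internally duplicated substructure
#'
#' Builds a chain containing the same rigid block twice (second copy rotated
#' and displaced, joined by a loop). Used to probe whether node-level
#' embeddings recognize repeated tertiary motifs irrespective of sequence
#' position.
#'
#' @param block_length residues per block copy.
#' @param seed integer seed.
#' @return List with `trace` (a [ca_trace]), `block1` and `block2`
#'   (integer index vectors of the two copies).
#' @export
make_duplicated_motif <- function(block_length = 25, seed = 1) {
  stopifnot(block_length >= 10)
  with_seed(seed, {
    block <- build_template(block_length)
    loop_len <- 6L
    r_max <- 4.2 * (2 * block_length)^(1 / 3) + 10
    chain <- block
    chain <- append_element(chain, loop_walk(loop_len), r_max)
    # second copy: same internal geometry, new orientation
    p_last <- chain[nrow(chain), ]
    d <- pick_direction(p_last, 10, r_max)
    rot <- random_rotation()
    b2 <- block %*% t(rot)
    b2 <- sweep(b2, 2L, p_last + 3.8 * d - b2[1L, ], "+")
    chain <- rbind(chain, b2)
    n <- nrow(chain)
    list(trace = ca_trace(chain, id = sprintf("dup_motif_s%d", seed)),
         block1 = seq_len(block_length),
         block2 = (n - block_length + 1L):n)
  })
}
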