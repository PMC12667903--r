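# shared fixture builders: plain-text PDB snippets, random-walk traces,
# rigid motions, small numeric utilities

cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_move <- function(coords, rot = rand_rotation(), shift = runif(3, -30, 30)) {
  sweep(coords %*% t(rot), 2, shift, "+")
}

# smooth random walk with 3.8 A steps (non-compact decoy backbone)
random_walk_trace <- function(n, seed, id = sprintf("walk%d", seed)) {
  set.seed(seed)
  p <- matrix(0, n, 3)
  d <- c(1, 0, 0)
  for (i in 2:n) {
    d <- 0.7 * d + 0.5 * rnorm(3)
    d <- d / sqrt(sum(d^2))
    p[i, ] <- p[i - 1, ] + 3.8 * d
  }
  ca_trace(p, id = id)
}

# fixed-width PDB ATOM record for a Calpha
pdb_ca_line <- function(serial, resno, x, y, z, alt = " ", occ = 1) {
  sprintf("ATOM  %5d  CA %1sGLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, alt, resno, x, y, z, occ, 0)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
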