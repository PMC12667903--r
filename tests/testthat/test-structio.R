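test_that("reader rejects short chains and preserves file order", {
  xs <- 3.8 * (0:3)
  p4 <- write_pdb_fixture(sapply(1:4, function(i)
    pdb_ca_line(i, i, xs[i], 0, 0)))
  expect_error(read_ca_trace(p4), "fewer than 5")

  xs <- 3.8 * (0:5)
  p6 <- write_pdb_fixture(sapply(1:6, function(i)
    pdb_ca_line(i, i, xs[i], 1 * i, 0)))
  tr <- read_ca_trace(p6)
  expect_s3_class(tr, "ca_trace")
  expect_equal(trace_length(tr), 6L)
  expect_equal(tr$coords[, 1], xs, tolerance = 1e-6)
  expect_equal(tr$coords[, 2], 1 * (1:6), tolerance = 1e-6)

  expect_error(read_ca_trace(tempfile()), "not found")
})

test_that("alternate locations resolve to the highest-occupancy Calpha", {
  lines <- c(
    pdb_ca_line(1, 1, 0.0, 0, 0),
    pdb_ca_line(2, 2, 3.8, 0, 0),
    pdb_ca_line(3, 3, 7.6, 0, 0, alt = "A", occ = 0.4),
    pdb_ca_line(4, 3, 7.9, 0, 0, alt = "B", occ = 0.6),
    pdb_ca_line(5, 4, 11.4, 0, 0),
    pdb_ca_line(6, 5, 15.2, 0, 0),
    pdb_ca_line(7, 6, 19.0, 0, 0))
  tr <- read_ca_trace(write_pdb_fixture(lines))
  expect_equal(trace_length(tr), 6L)
  expect_equal(unname(tr$coords[3, 1]), 7.9,
               tolerance = 1e-6)  # occupancy 0.6 wins
})

test_that("writer round-trips coordinates at PDB precision", {
  tr <- random_walk_trace(100, seed = 11)
  path <- tempfile(fileext = ".pdb")
  write_ca_trace(tr, path)
  expect_equal(sum(grepl("^ATOM", readLines(path))), 100L)
  back <- read_ca_trace(path)
  expect_equal(back$coords, tr$coords, tolerance = 1e-3,
               ignore_attr = TRUE)

  big <- tr
  big$coords[1, 1] <- 12000
  expect_error(write_ca_trace(big, tempfile(fileext = ".pdb")),
               "overflow")
})

test_that("syncp reorders cyclically, conserves coordinates, and inverts", {
  tr <- random_walk_trace(5, seed = 3)
  rec <- syncp(tr, 1)
  expect_equal(rec$child$coords, tr$coords[c(2, 3, 4, 5, 1), ],
               ignore_attr = TRUE)
  expect_equal(rec$k, 1L)
  expect_identical(syncp(tr, 0)$child$coords, tr$coords)
  expect_error(syncp(tr, 5), "0 <= k < n")
  expect_error(syncp(tr, -1), "0 <= k < n")

  set.seed(20)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    t0 <- random_walk_trace(n, seed = 100 + rep)
    k <- sample(0:(n - 1), 1)
    child <- syncp(t0, k)$child
    back <- if (k == 0) child else syncp(child, n - k)$child
    expect_identical(back$coords, t0$coords)
    expect_equal(child$coords[order(child$coords[, 1]), ],
                 t0$coords[order(t0$coords[, 1]), ])  # same multiset
  }
})

test_that("enumerate_syncps yields one record per cut, one multiset", {
  tr <- random_walk_trace(5, seed = 8)
  recs <- enumerate_syncps(tr)
  expect_length(recs, 5L)
  expect_equal(vapply(recs, function(r) r$k, 0L), 0:4)
  key <- function(m) paste(sort(round(as.numeric(m), 6)), collapse = ",")
  expect_length(unique(vapply(recs, function(r) key(r$child$coords), "")),
                1L)
  # all-vs-all scoring over enumerations of two traces is n * m comparisons
  t2 <- random_walk_trace(7, seed = 9)
  grid <- expand.grid(a = seq_along(recs),
                      b = seq_along(enumerate_syncps(t2)))
  expect_equal(nrow(grid), 5L * 7L)
})

test_that("synthetic families are deterministic and rigidly consistent", {
  f0 <- make_synthetic_family(4, 30, 0, seed = 21)
  for (m in f0[-1]) {
    kb <- kabsch(f0[[1]]$coords, m$coords)
    expect_lt(kb$rmsd, 1e-9)  # noise-free members superpose exactly
  }
  f1 <- make_synthetic_family(4, 30, 0.4, seed = 22)
  f2 <- make_synthetic_family(4, 30, 0.4, seed = 22)
  expect_identical(lapply(f1, `[[`, "coords"), lapply(f2, `[[`, "coords"))
  expect_true(all(vapply(f1, function(t) t$labels, "") == f1[[1]]$labels))
  # prefix stability: first members unchanged when more members are drawn
  f3 <- make_synthetic_family(6, 30, 0.4, seed = 22)
  expect_identical(f3[[2]]$coords, f1[[2]]$coords)
})

test_that("within-family spread is below between-family spread", {
  fa <- make_synthetic_family(5, 40, 0.5, seed = 31)
  fb <- make_synthetic_family(5, 40, 0.5, seed = 32)
  within <- c()
  for (i in 1:4) for (j in (i + 1):5)
    within <- c(within, kabsch(fa[[i]]$coords, fa[[j]]$coords)$rmsd)
  between <- c()
  for (i in 1:5) for (j in 1:5)
    between <- c(between, kabsch(fa[[i]]$coords, fb[[j]]$coords)$rmsd)
  frac <- mean(outer(within, between, "<"))
  expect_gte(frac, 0.95)
})

test_that("benchmark plants equal-length, multiset-conserving CP pairs", {
  bm <- make_cp_benchmark(4, 3, 40, 0, seed = 5)
  ids <- vapply(bm$traces, function(t) t$id, "")
  expect_true(all(c(bm$cp_pairs$id_a, bm$cp_pairs$id_b,
                    bm$decoy_pairs$id_a, bm$decoy_pairs$id_b) %in% ids))
  pk <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_length(intersect(pk(bm$cp_pairs$id_a, bm$cp_pairs$id_b),
                          pk(bm$decoy_pairs$id_a, bm$decoy_pairs$id_b)), 0L)
  key <- function(m) paste(sort(round(as.numeric(m), 6)), collapse = ",")
  for (r in seq_len(nrow(bm$cp_pairs))) {
    a <- bm$traces[[match(bm$cp_pairs$id_a[r], ids)]]
    b <- bm$traces[[match(bm$cp_pairs$id_b[r], ids)]]
    expect_equal(trace_length(a), trace_length(b))
    expect_identical(key(a$coords), key(b$coords))  # noise_sd = 0
  }
  bm2 <- make_cp_benchmark(4, 3, 40, 0, seed = 5)
  expect_identical(lapply(bm$traces, `[[`, "coords"),
                   lapply(bm2$traces, `[[`, "coords"))
})

test_that("planted cut offsets are recovered by exhaustive superposition", {
  bm <- make_cp_benchmark(3, 3, 36, 0.2, seed = 6)
  ids <- vapply(bm$traces, function(t) t$id, "")
  for (r in seq_len(nrow(bm$cp_pairs))) {
    a <- bm$traces[[match(bm$cp_pairs$id_a[r], ids)]]
    b <- bm$traces[[match(bm$cp_pairs$id_b[r], ids)]]
    n <- trace_length(a)
    rmsds <- vapply(0:(n - 1), function(s) {
      shifted <- syncp(a, s)$child$coords
      kabsch(shifted, b$coords)$rmsd
    }, 0)
    expect_equal(which.min(rmsds) - 1L, bm$cp_pairs$k[r])
  }
})
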