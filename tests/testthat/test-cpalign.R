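test_that("kabsch recovers planted rigid motions with proper rotations", {
  X <- random_walk_trace(30, seed = 41)$coords
  self <- kabsch(X, X)
  expect_lt(self$rmsd, 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  set.seed(42)
  R <- rand_rotation(); t <- c(5, -3, 12)
  Y <- sweep(X %*% t(R), 2, t, "+")
  kb <- kabsch(X, Y)
  expect_lt(kb$rmsd, 1e-9)
  expect_equal(kb$rotation, t(R), tolerance = 1e-9)  # X %*% rot + t == Y
  expect_equal(det(kb$rotation), 1, tolerance = 1e-9)

  # mirror image: rotation stays proper, fit is imperfect
  Ym <- X %*% diag(c(-1, 1, 1))
  km <- kabsch(X, Ym)
  expect_gt(km$rmsd, 0.1)
  expect_equal(det(km$rotation), 1, tolerance = 1e-9)

  collinear <- cbind(1:5, 0, 0)
  expect_warning(kabsch(collinear, collinear), "collinear")
  expect_error(kabsch(X[1:2, ], X[1:2, ]), "m >= 3")
})

test_that("d0 follows the TM-score length scale with its 0.5 A floor", {
  expect_equal(tm_d0(36), 1.24 * 21^(1 / 3) - 1.8, tolerance = 1e-9)
  expect_equal(tm_d0(36), 1.6210, tolerance = 1e-3)
  expect_equal(tm_d0(17), 0.5)   # 1.24 * 2^(1/3) - 1.8 < 0 clamps
  expect_equal(tm_d0(15), 0.5)
  expect_equal(tm_d0(10), 0.5)
})

test_that("tm_score is exact on identical structures", {
  X <- random_walk_trace(40, seed = 43)$coords
  mapping <- cbind(1:40, 1:40)
  expect_equal(tm_score(X, X, mapping, 40), 1, tolerance = 1e-9)
  # rigid motion of one copy does not change the score
  set.seed(44)
  Y <- rigid_move(X)
  expect_equal(tm_score(X, Y, mapping, 40), 1, tolerance = 1e-6)
  expect_error(tm_score(X, X, mapping[0, , drop = FALSE], 40), "empty")
})

test_that("alignment DP equals exhaustive monotone-mapping enumeration", {
  set.seed(45)
  for (rep in 1:12) {
    n <- sample(4:8, 1); m <- sample(4:8, 1)
    S <- matrix(runif(n * m), n, m)
    dp <- cpscan:::cpp_dp(S, -0.6)
    expect_equal(dp$score, brute_dp_score(S, -0.6), tolerance = 1e-9)
    # returned mapping is monotone, one-to-one, and scores what DP claims
    expect_true(all(diff(dp$qi) > 0) && all(diff(dp$tj) > 0))
    sc <- sum(S[cbind(dp$qi, dp$tj)])
    if (length(dp$qi) > 1) {
      sc <- sc - 0.6 * sum((diff(dp$qi) > 1) + (diff(dp$tj) > 1))
    }
    expect_equal(sc, dp$score, tolerance = 1e-9)
  }
  # also on score matrices from real (tiny) coordinate sets
  for (rep in 1:4) {
    A <- random_walk_trace(8, seed = 500 + rep)$coords
    B <- random_walk_trace(7, seed = 600 + rep)$coords
    d0 <- tm_d0(7)
    S <- 1 / (1 + (as.matrix(dist(rbind(A, B)))[1:8, 9:15] / d0)^2)
    dp <- cpscan:::cpp_dp(S, -0.6)
    expect_equal(dp$score, brute_dp_score(S, -0.6), tolerance = 1e-9)
  }
})

test_that("self-alignment is exact; nested fragments use min-normalization", {
  tr <- random_walk_trace(60, seed = 46)
  al <- align(tr, tr)
  expect_equal(al$tm_min, 1, tolerance = 1e-6)
  expect_equal(al$mapping, cbind(1:60, 1:60), ignore_attr = TRUE)
  expect_lt(al$rmsd, 1e-9)

  half <- ca_trace(tr$coords[1:30, ], id = "half")
  ah <- align(tr, half)
  expect_gte(ah$tm_target, 0.95)        # the fragment is fully explained
  expect_lt(ah$tm_query, 0.65)          # the whole chain is not
  expect_equal(ah$tm_min, ah$tm_query)
  expect_error(align(half, random_walk_trace(10, seed = 1)), "20 residues")
})

test_that("alignment score is symmetric within heuristic slack", {
  for (rep in 1:3) {
    a <- make_synthetic_family(2, 45, 0.8, seed = 700 + rep)[[1]]
    b <- make_synthetic_family(2, 45, 0.8, seed = 800 + rep)[[1]]
    expect_equal(align(a, b)$tm_min, align(b, a)$tm_min, tolerance = 0.02)
  }
})

test_that("duplicate-and-align recovers planted circular permutants", {
  set.seed(47)
  for (rep in 1:5) {
    tr <- make_synthetic_family(1, 50, 0, seed = 900 + rep)[[1]]
    k <- sample(10:40, 1)
    child <- syncp(tr, k)$child
    child$coords <- rigid_move(child$coords)
    acp <- align_cp(tr, child)
    expect_gte(acp$tm_min, 0.99)
    expect_equal(acp$cp_offset %% 50, k %% 50)
    expect_true(acp$cp_mode)
    # one-to-one on original residues, monotone in the shifted frame
    expect_false(any(duplicated(acp$mapping[, 1])))
    expect_true(all(diff(acp$mapping[, 1]) > 0))
  }
  tr <- make_synthetic_family(1, 50, 0, seed = 950)[[1]]
  expect_lte(abs(align_cp(tr, tr)$tm_min - align(tr, tr)$tm_min), 0.01)
})

test_that("delta_cp flags planted permutants and clears non-CP pairs", {
  tr <- make_synthetic_family(1, 44, 0, seed = 51)[[1]]
  v <- delta_cp(tr, syncp(tr, 22)$child)
  expect_true(v$is_cp)
  expect_gt(v$tm_cp, 0.5)
  expect_gt(v$delta_cp, 0)

  twin <- ca_trace(rigid_move(tr$coords), id = "twin")
  set.seed(52)
  v0 <- delta_cp(tr, twin)
  expect_false(v0$is_cp)
  expect_lt(abs(v0$delta_cp), 0.01)

  for (rep in 1:3) {
    d1 <- random_walk_trace(44, seed = 1100 + rep)
    d2 <- random_walk_trace(44, seed = 1200 + rep)
    vd <- delta_cp(d1, d2)
    expect_lt(vd$tm_cp, 0.5)
    expect_false(vd$is_cp)
  }
})
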