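test_that("supervised contrastive loss matches closed forms", {
  Z <- matrix(rep(c(1, 2, 3), 4), 4, byrow = TRUE)
  expect_equal(supcon_loss(Z, c("a", "a", "b", "b")), log(3),
               tolerance = 1e-12)
  # within-class identical, between-class orthogonal, sharp temperature
  Zs <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_lt(supcon_loss(Zs, c("a", "a", "b", "b"), temperature = 0.05),
            1e-5)
  # symmetric under class relabeling
  set.seed(1)
  Zr <- matrix(rnorm(12), 4)
  expect_equal(supcon_loss(Zr, c("a", "a", "b", "b")),
               supcon_loss(Zr, c("q", "q", "z", "z")))
  expect_error(supcon_loss(Zr, c("a", "b", "c", "d")), "no anchor")
})

test_that("analytic supcon gradient matches numerical differentiation", {
  set.seed(5)
  Z <- matrix(rnorm(18), 6, 3)
  lab <- c("a", "a", "b", "b", "c", "c")
  g <- cpscan:::supcon_loss_grad(Z, lab, 0.1)$grad
  num <- matrix(0, 6, 3)
  eps <- 1e-6
  for (i in 1:6) for (j in 1:3) {
    zp <- Z; zp[i, j] <- zp[i, j] + eps
    zm <- Z; zm[i, j] <- zm[i, j] - eps
    num[i, j] <- (supcon_loss(zp, lab, 0.1) -
                    supcon_loss(zm, lab, 0.1)) / (2 * eps)
  }
  expect_lt(max(abs(num - g)), 1e-4)
})

test_that("embeddings are invariant to rigid motion and edge storage", {
  tr <- random_walk_trace(30, seed = 17)
  g <- build_graph(tr)
  model <- init_model(model_config(seed = 99))
  z <- encode(g, model)
  expect_true(all(is.finite(z)) && any(z != 0))
  set.seed(31)
  for (rep in 1:10) {
    g2 <- build_graph(ca_trace(rigid_move(tr$coords), id = "mv"))
    expect_gte(cosv(z, encode(g2, model)), 0.999)
  }
  # shuffling stored edge order changes nothing
  gs <- g
  perm <- sample(nrow(g$edges))
  gs$edges <- g$edges[perm, , drop = FALSE]
  gs$edge_d2 <- g$edge_d2[perm]
  expect_equal(as.numeric(encode(gs, model)), as.numeric(z),
               tolerance = 1e-12)
})

test_that("noise-free family members embed identically", {
  fam <- make_synthetic_family(3, 30, 0, seed = 55)
  model <- init_model(model_config(seed = 1))
  zs <- lapply(fam, function(t) encode(build_graph(t), model))
  expect_gte(cosv(zs[[1]], zs[[2]]), 0.99999)
  expect_gte(cosv(zs[[1]], zs[[3]]), 0.99999)
})

test_that("mean-pooled node embeddings reproduce the structure embedding", {
  tr <- random_walk_trace(24, seed = 23)
  g <- build_graph(tr)
  model <- init_model(model_config(seed = 3))
  H <- node_embeddings(g, model)
  expect_equal(nrow(H), 24L)
  z <- colMeans(H) %*% model$params$W_out + model$params$b_out
  expect_equal(as.numeric(z), as.numeric(encode(g, model)),
               tolerance = 1e-10)
  # every node row is rigid-motion invariant
  set.seed(7)
  H2 <- node_embeddings(build_graph(ca_trace(rigid_move(tr$coords),
                                             id = "mv")), model)
  expect_equal(H2, H, tolerance = 1e-9)
})

test_that("contrastive training reduces the loss on a small family set", {
  fams <- lapply(1:10, function(j)
    make_synthetic_family(4, 40, 0.3, seed = 400 + j,
                          label = sprintf("c.%d.1.1", j)))
  traces <- unlist(fams, recursive = FALSE)
  cfg <- model_config(n_layers = 2, hidden_dim = 16, embed_dim = 16,
                      epochs = 15, batch_families = 5,
                      members_per_family = 3, seed = 11)
  m <- train(traces, cfg)
  lg <- m$training_log
  expect_lt(tail(lg$loss, 1), lg$loss[1])
  # deterministic for a fixed seed
  m2 <- train(traces, cfg)
  expect_identical(m$params, m2$params)
  expect_error(train(traces[1:4][c(1, 2)], cfg), "2 families")
})

test_that("retrieval sensitivity counts true positives above the first
           false positive", {
  expect_equal(retrieval_sensitivity(
    "a.1.1.1", c("a.1.1.1", "a.1.1.1", "b.2.1.1", "a.1.1.1"), "family"),
    2 / 3)
  expect_equal(retrieval_sensitivity(
    "a.1.1.1", c("a.1.1.1", "a.1.1.1", "b.2.1.1"), "family"), 1)
  expect_equal(retrieval_sensitivity(
    "a.1.1.1", c("b.2.1.1", "a.1.1.1"), "family"), 0)
  # no true positives at the level: undefined, not zero
  expect_true(is.na(retrieval_sensitivity(
    "a.1.1.1", c("b.2.1.1", "b.2.1.1"), "superfamily")))
  # level semantics: same family does not count at superfamily level
  expect_equal(retrieval_sensitivity(
    "a.1.1.1", c("a.1.1.2", "a.1.1.1", "b.2.1.1"), "superfamily"), 1)
  expect_equal(retrieval_sensitivity(
    "a.1.1.1", c("a.1.2.1", "b.2.1.1", "a.1.2.1"), "fold"), 1 / 2)
})
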