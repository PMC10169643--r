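test_that("adjacency normalization matches hand-computed cases", {
  expect_equal(unname(normalize_adjacency(matrix(1, 1, 1))), matrix(1, 1, 1),
               ignore_attr = TRUE)
  s <- 0.4
  G <- rbind(c(1, s), c(s, 1))
  expect_equal(unclass(normalize_adjacency(G)), (G + diag(2)) / (2 + s),
               ignore_attr = TRUE)
  # no edges at all: self-loops only
  expect_equal(unclass(normalize_adjacency(matrix(0, 3, 3))), diag(3),
               ignore_attr = TRUE)
  # identical degrees => every entry is (G+I)_ij / d
  G <- matrix(0.5, 4, 4); diag(G) <- 1
  d <- 1 + rowSums(G)[1]
  expect_equal(unclass(normalize_adjacency(G)), (G + diag(4)) / d,
               ignore_attr = TRUE)
  expect_error(normalize_adjacency(matrix(1:6, 2)), class = "ldra_contract_error")
})

test_that("graph convolution reduces to identity and normalises rows", {
  X <- matrix(c(1, 2, 0, 3), 2, 2)
  out <- gcn_encode(X, diag(2), diag(2), diag(2), activation = "identity")
  expect_equal(out, X)
  out <- gcn_encode(X, diag(2), diag(2), diag(2), activation = "row_softmax")
  expect_equal(rowSums(out), c(1, 1), tolerance = 1e-8)
})

test_that("graph convolution agrees with the dense oracle", {
  for (trial in 1:20) {
    k <- withr::with_seed(trial, sample(2:8, 1))
    withr::with_seed(trial + 100, {
      G <- crossprod(matrix(runif(k * k), k)) / k
      G <- G / max(G); diag(G) <- 1
      X <- matrix(rnorm(k * 3), k, 3)
      W0 <- matrix(rnorm(3 * 4), 3, 4)
      W1 <- matrix(rnorm(4 * 2), 4, 2)
    })
    Ahat <- normalize_adjacency(G)
    for (act in c("identity", "relu", "row_softmax")) {
      expect_equal(gcn_encode(X, Ahat, W0, W1, act),
                   brute_gcn(X, unclass(Ahat), W0, W1, act),
                   tolerance = 1e-6)
    }
  }
})

test_that("attention logits follow the concatenated linear form", {
  X <- rbind(c(1, 0), c(0, 2), c(1, 1))
  W <- diag(2)
  expect_equal(attention_logits(X, W, rep(0, 4)), matrix(0, 3, 3))
  # identical features give a constant logit matrix
  Xc <- matrix(1, 3, 2)
  e <- attention_logits(Xc, W, c(0.3, -0.2, 0.5, 0.1))
  expect_equal(max(e) - min(e), 0)
  # two-node hand computation
  X2 <- rbind(c(1, 0), c(0, 1))
  a <- c(1, 2, 3, 4)
  e <- attention_logits(X2, diag(2), a, leaky_slope = 0.2)
  lr <- function(v) ifelse(v > 0, v, 0.2 * v)
  expect_equal(e, rbind(c(lr(1 + 3), lr(1 + 4)), c(lr(2 + 3), lr(2 + 4))))
  # negative pre-activation picks up the leaky slope
  e <- attention_logits(X2, diag(2), c(-1, 0, -2, 0), leaky_slope = 0.2)
  expect_equal(e[1, 1], 0.2 * (-3))
})

test_that("attention normalization is a masked stabilised softmax", {
  # single neighbour
  expect_equal(attention_normalize(matrix(5, 1, 1))[1, 1], 1)
  # four equal logits
  expect_equal(attention_normalize(matrix(2, 4, 4))[1, ], rep(0.25, 4))
  # closed form for logits (0, log 2)
  a <- attention_normalize(rbind(c(0, log(2)), c(0, log(2))))
  expect_equal(a[1, ], c(1 / 3, 2 / 3))
  # masked entries are exactly zero and rows still sum to 1
  mask <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE))
  a <- attention_normalize(matrix(rnorm(9), 3), mask)
  expect_equal(unname(a[!mask]), rep(0, 2))
  expect_equal(rowSums(a), rep(1, 3), tolerance = 1e-8)
  # extreme logits do not overflow thanks to max-subtraction
  a <- attention_normalize(matrix(c(1000, 990), 1, 2))
  expect_equal(a[1, ], c(1, exp(-10)) / (1 + exp(-10)))
  expect_error(attention_normalize(matrix(0, 2, 2), matrix(FALSE, 2, 2)),
               class = "ldra_contract_error")
})

test_that("an isolated self-attending node passes its features through", {
  X <- matrix(c(0.5, 1.5), 1, 2)  # nonnegative, so the ELU is the identity
  heads <- list(list(W = diag(2), a = rnorm(4)))
  out <- gat_layer(X, matrix(1, 1, 1), heads, fusion = "average")
  expect_equal(out, X)
})

test_that("head fusion controls the output width", {
  X <- matrix(rnorm(6 * 8), 6, 8)
  G <- diag(6) * 0 + 0.5; diag(G) <- 1
  heads <- rand_heads(8, 8, 25, seed = 3)
  expect_equal(ncol(gat_layer(X, G, heads, fusion = "concat")), 200)
  expect_equal(ncol(gat_layer(X, G, heads, fusion = "average")), 25)
})

test_that("the attention layer agrees with the per-node oracle", {
  for (trial in 1:20) {
    withr::with_seed(trial, {
      k <- sample(3:8, 1)
      G <- crossprod(matrix(runif(k * k), k)) / k
      G <- G / max(G); diag(G) <- 1
      X <- matrix(rnorm(k * 4), k, 4)
    })
    heads <- rand_heads(3, 4, 2, seed = trial + 50)
    for (fusion in c("concat", "average")) {
      got <- gat_layer(X, G, heads, fusion = fusion)
      ref <- brute_gat(X, matrix(TRUE, k, k), heads, fusion, 0.2)
      expect_equal(got, ref, tolerance = 1e-6)
      # sparsified neighbourhood
      got2 <- gat_layer(X, G, heads, fusion = fusion, knn = 2)
      mask2 <- ldra:::neighborhood_mask(G, 2)
      expect_equal(got2, brute_gat(X, mask2, heads, fusion, 0.2),
                   tolerance = 1e-6)
    }
  }
})

test_that("convolution and attention layers are equivariant to node relabelling", {
  # permuting the node order of G and the rows of X permutes the outputs
  # identically (the feature axis of X is left alone)
  withr::with_seed(22, {
    k <- 7
    G <- crossprod(matrix(runif(k * k), k)) / k
    G <- G / max(G); diag(G) <- 1
    X <- matrix(rnorm(k * 4), k, 4)
    W0 <- matrix(rnorm(4 * 5), 4, 5)
    W1 <- matrix(rnorm(5 * 3), 5, 3)
    perm <- sample(k)
  })
  P <- diag(k)[perm, ]
  Gp <- G[perm, perm]
  out1 <- gcn_encode(X, normalize_adjacency(G), W0, W1, "identity")
  out2 <- gcn_encode(X[perm, ], normalize_adjacency(Gp), W0, W1, "identity")
  expect_equal(out2, out1[perm, ], tolerance = 1e-8)

  heads <- rand_heads(2, 4, 3, seed = 23)
  for (fusion in c("concat", "average")) {
    g1 <- gat_layer(X, G, heads, fusion = fusion)
    g2 <- gat_layer(X[perm, ], Gp, heads, fusion = fusion)
    expect_equal(g2, g1[perm, ], tolerance = 1e-8)
  }
})

test_that("the decoder is an elementwise sigmoid of inner products", {
  expect_equal(score_associations(matrix(0, 2, 3), matrix(0, 4, 3)),
               matrix(0.5, 2, 4))
  expect_equal(score_associations(matrix(log(3), 1, 1), matrix(1, 1, 1))[1, 1],
               0.75)
  El <- withr::with_seed(2, matrix(rnorm(15), 5, 3))
  Ed <- withr::with_seed(3, matrix(rnorm(9), 3, 3))
  ref <- matrix(0, 5, 3)
  for (i in 1:5) for (j in 1:3) ref[i, j] <- plogis(sum(El[i, ] * Ed[j, ]))
  S <- score_associations(El, Ed)
  expect_equal(S, ref, tolerance = 1e-10)
  expect_true(all(S > 0 & S < 1))
  # negating one side complements the scores
  expect_equal(score_associations(El, -Ed), 1 - S, tolerance = 1e-12)
  expect_error(score_associations(El, matrix(0, 2, 2)),
               class = "ldra_contract_error")
})

test_that("embedding and parameter shapes follow the configuration", {
  cfg <- ldra_control(epochs = 0)
  emb <- ldra_encode(rand_am(12, 6, seed = 5), cfg)
  expect_equal(dim(emb$lnc), c(12L, 200L))
  expect_equal(dim(emb$drug), c(6L, 200L))

  # stacked attention: hidden layers concatenate K * c columns
  cfg4 <- ldra_control(epochs = 0, layers = 4)
  p <- ldra_params(12, 6, cfg4)
  expect_length(p$lnc$gat, 2)
  expect_equal(dim(p$lnc$gat[[1]]$heads[[1]]$W), c(200L, 25L))   # concat head
  expect_equal(dim(p$lnc$gat[[2]]$heads[[1]]$W), c(200L, 200L))  # average head
  am <- rand_am(12, 6, seed = 6)
  emb4 <- ldra_encode(am, cfg4)
  expect_equal(dim(emb4$lnc), c(12L, 200L))

  # shapes depend only on (m, n, config), not on the data values
  shapes <- function(p) rapply(p, dim, how = "unlist")
  expect_identical(shapes(ldra_params(12, 6, cfg4)), shapes(p))
  cfgv <- ldra_control(epochs = 0, variant = "gcn_only")
  expect_equal(dim(ldra_encode(am, cfgv)$lnc), c(12L, 200L))
  cfgg <- ldra_control(epochs = 0, variant = "gat_only")
  expect_equal(dim(ldra_encode(am, cfgg)$drug), c(6L, 200L))
})

test_that("attention rows sum to one at every layer and head", {
  am <- rand_am(9, 5, density = 0.4, seed = 8)
  for (cfg in list(ldra_control(epochs = 0, layers = 4, embedding_size = 8,
                                gcn_hidden = 6, heads = 4, seed = 2),
                   ldra_control(epochs = 0, variant = "gat_only",
                                embedding_size = 6, heads = 3, seed = 2))) {
    enc <- ldra_encode(am, cfg, attention = TRUE)
    for (side in c("lnc", "drug")) {
      layers <- enc$attention[[side]]
      expect_gt(length(layers), 0)
      for (l in layers) for (alpha in l) {
        expect_equal(unname(rowSums(alpha)), rep(1, nrow(alpha)),
                     tolerance = 1e-8)
        expect_true(all(alpha >= 0))
      }
    }
  }
})
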