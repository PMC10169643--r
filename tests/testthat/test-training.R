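test_that("reconstruction loss variants match their closed forms", {
  am <- as_association_matrix(rbind(c(1, 0), c(0, 1)))
  # perfect reconstruction (up to clamping)
  P <- am$A
  expect_lt(reconstruction_loss(P, am, variant = "bce"), 1e-6)
  expect_equal(reconstruction_loss(P, am, variant = "mse"), 0)
  expect_equal(reconstruction_loss(P, am, variant = "literal_sum"), 0)
  # a single masked entry with A = 1 and score 0.5 costs log 2 under BCE
  expect_equal(reconstruction_loss(matrix(0.5, 2, 2), am, mask = 1L,
                                   variant = "bce"), log(2))
  expect_equal(reconstruction_loss(matrix(0.5, 2, 2), am, mask = 1L,
                                   variant = "mse"), 0.25)
  # the literal signed sum can go negative (why it is diagnostic only)
  expect_lt(reconstruction_loss(matrix(0.1, 2, 2), am,
                                variant = "literal_sum"), 0)
  expect_error(reconstruction_loss(P, am, mask = integer(0)),
               class = "ldra_contract_error")
})

test_that("zero epochs returns initialised parameters and empty history", {
  am <- rand_am(6, 4, seed = 2)
  cfg <- tiny_cfg(epochs = 0)
  fit <- ldra(am, cfg)
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$params, ldra_params(6, 4, cfg))
})

test_that("training is deterministic given the seed", {
  am <- rand_am(8, 5, density = 0.35, seed = 3)
  cfg <- tiny_cfg(epochs = 10)
  f1 <- ldra(am, cfg)
  f2 <- ldra(am, cfg)
  expect_equal(f1$history$loss, f2$history$loss, tolerance = 1e-6)
  expect_equal(f1$scores, f2$scores, tolerance = 1e-6)
  f3 <- ldra(am, tiny_cfg(epochs = 10, seed = 99))
  expect_false(identical(f3$scores, f1$scores))
})

test_that("the loss descends on planted-structure data", {
  am <- simulate_associations(50, 10, blocks = 2, p_in = 0.6, p_out = 0.05,
                              seed = 0)
  cfg <- ldra_control(epochs = 200, embedding_size = 32, gcn_hidden = 32,
                      heads = 4, seed = 0)
  fit <- ldra(am, cfg)
  expect_lt(fit$history$loss[200], fit$history$loss[1])

  # trend check across seeds with a faster learning rate
  descended <- vapply(1:5, function(s) {
    amx <- simulate_associations(25, 8, blocks = 2, p_in = 0.7, p_out = 0.05,
                                 seed = s)
    f <- ldra(amx, ldra_control(epochs = 60, learning_rate = 1e-3,
                                embedding_size = 16, gcn_hidden = 16,
                                heads = 2, seed = s))
    median(tail(f$history$loss, 10)) < median(head(f$history$loss, 10))
  }, logical(1))
  expect_gte(sum(descended), 4)
})

test_that("training needs both classes in the mask", {
  am <- rand_am(5, 4, seed = 4)
  pos <- which(as.vector(am$A) == 1)
  expect_error(ldra(am, tiny_cfg(), train_mask = pos),
               class = "ldra_contract_error")
})

test_that("test-fold entries cannot leak into training", {
  am <- simulate_associations(15, 6, blocks = 2, p_in = 0.7, p_out = 0.1,
                              seed = 12)
  folds <- make_folds(am, k = 3, mode = "balanced", seed = 5)
  fd <- folds[[1]]
  m <- nrow(am$A)
  mask <- c(ldra:::pairs_to_linear(fd$train_pos, m),
            ldra:::pairs_to_linear(fd$train_neg, m))
  test_lin <- ldra:::pairs_to_linear(fd$test_pos, m)

  censor <- function(base) {
    out <- base
    out$A[test_lin] <- 0
    out
  }
  cfg <- tiny_cfg(epochs = 1)
  f_ref <- ldra(censor(am), cfg, train_mask = mask)

  # flip a held-out positive in the raw matrix: after censoring, epoch-1
  # training loss must be bit-identical
  am_pert <- am
  am_pert$A[test_lin[1]] <- 0
  f_pert <- ldra(censor(am_pert), cfg, train_mask = mask)
  expect_identical(f_ref$history$loss[1], f_pert$history$loss[1])

  # flip a test negative to positive in the raw matrix; it is excluded from
  # the mask and zeroing-by-construction does not apply, so censor it too
  tneg <- ldra:::pairs_to_linear(fd$test_neg, m)[1]
  am_pert2 <- am
  am_pert2$A[tneg] <- 1
  am_pert2$A[test_lin] <- 0
  am_pert2$A[tneg] <- 0
  f_pert2 <- ldra(am_pert2, cfg, train_mask = mask)
  expect_identical(f_ref$history$loss[1], f_pert2$history$loss[1])
})

test_that("parameter tensor shapes depend only on dimensions and config", {
  cfg <- tiny_cfg(layers = 4, embedding_size = 8, heads = 2)
  shapes <- function(p) rapply(p, function(x) paste(dim(x) %||% length(x), collapse = "x"),
                               how = "unlist")
  `%||%` <- function(a, b) if (is.null(a)) b else a
  s1 <- shapes(ldra(rand_am(9, 4, density = 0.2, seed = 1), cfg)$params)
  s2 <- shapes(ldra(rand_am(9, 4, density = 0.6, seed = 8), cfg)$params)
  expect_identical(s1, s2)
})

test_that("per-epoch negative resampling draws from the supplied pool", {
  am <- rand_am(10, 5, density = 0.3, seed = 6)
  pos <- which(as.vector(am$A) == 1)
  neg <- which(as.vector(am$A) == 0)
  cfg <- tiny_cfg(epochs = 5, resample_negatives = TRUE)
  mask <- c(pos, neg[1:length(pos)])
  f1 <- ldra(am, cfg, train_mask = mask, neg_pool = neg)
  f2 <- ldra(am, cfg, train_mask = mask, neg_pool = neg)
  expect_equal(f1$history$loss, f2$history$loss)  # still seed-deterministic
  expect_equal(nrow(f1$history), 5)
})
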