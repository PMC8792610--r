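test_that("adjacency normalisation handles limit cases and stays symmetric", {
  expect_equal(normalize_adjacency(matrix(0, 4, 4)), diag(4))
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2))  # degrees are 2
  for (k in 1:10) {
    A <- rand_adjacency(15, seed = 70 + k)
    Ah <- normalize_adjacency(A)
    expect_lt(max(abs(Ah - t(Ah))), 1e-12)
    expect_true(all(Ah >= 0))
  }
  expect_error(normalize_adjacency(matrix(-1, 2, 2)), "non-negative")
})

test_that("graph convolution reduces to an MLP when the graph is empty", {
  n <- 8
  params <- withr::with_seed(1, list(W0 = matrix(rnorm(n * 5), n, 5),
                                     W1 = matrix(rnorm(5 * 4), 5, 4)))
  X <- withr::with_seed(2, matrix(rnorm(n * n), n, n))
  out <- gcn_forward(X, diag(n), params)
  ref <- pmax(pmax(X %*% params$W0, 0) %*% params$W1, 0)
  expect_equal(out, ref, tolerance = 1e-12)
  expect_equal(gcn_forward(X * 0, normalize_adjacency(rand_adjacency(n, 3)), params),
               matrix(0, n, 4))
  expect_error(gcn_forward(X[, 1:3], diag(n), params), "layer 1")
})

test_that("convolution is permutation-equivariant and readout order-invariant", {
  for (k in 1:100) {
    n <- 6 + (k %% 5)
    A <- rand_adjacency(n, seed = 100 + k, density = 0.8)
    Ah <- normalize_adjacency(A)
    X <- withr::with_seed(200 + k, matrix(rnorm(n * n), n, n))
    params <- withr::with_seed(300 + k,
      list(W0 = matrix(rnorm(n * 7), n, 7), W1 = matrix(rnorm(7 * 6), 7, 6)))
    perm <- withr::with_seed(400 + k, sample(n))
    P <- diag(n)[perm, ]
    H <- gcn_forward(X, Ah, params)
    Hp <- gcn_forward(P %*% X, P %*% Ah %*% t(P), params)
    expect_lt(max(abs(Hp - P %*% H)), 1e-6)
    expect_lt(max(abs(readout(Hp) - readout(H))), 1e-6)
  }
})

test_that("readout concatenates column means then maxima", {
  H <- matrix(c(1, 3, 2, -4), 2, 2)
  expect_equal(readout(H), c(2, -1, 3, 2))
  H32 <- withr::with_seed(5, matrix(rnorm(20 * 32), 20, 32))
  expect_length(readout(H32), 64)
  one <- matrix(1:4, 1, 4)
  expect_equal(readout(one), c(1:4, 1:4))  # mean = max for a single node
  expect_error(readout(matrix(numeric(0), 0, 3)), "empty")
})

test_that("fusion rescales blocks, zeroes dropped scales, and normalises output", {
  head <- mgrl:::mlp_init(c(8, 8, 4, 2), seed = 1)
  r1 <- withr::with_seed(2, rnorm(4))
  r2 <- withr::with_seed(3, rnorm(4))
  p_eq <- fuse_and_classify(list(a = r1, b = r2), fusion_config(), head)
  expect_equal(sum(p_eq), 1, tolerance = 1e-6)
  # alpha = (1, 0): second block is zeroed so its content cannot matter
  p10a <- fuse_and_classify(list(a = r1, b = r2),
                            fusion_config(alpha = c(1, 0)), head)
  p10b <- fuse_and_classify(list(a = r1, b = 99 + r2),
                            fusion_config(alpha = c(1, 0)), head)
  expect_equal(p10a, p10b, tolerance = 1e-12)
  expect_error(fusion_config(alpha = c(0.6, 0.6)), "sum to 1")
})

test_that("the full forward pass is deterministic and node-relabel invariant", {
  co <- tiny_cohort(n_subjects = 3, seed = 17, fine = 12, coarse = 6, t_n = 25)
  g <- cohort_graphs(co)
  params <- mgrl_init(c(coarse = 6L, fine = 12L), seed = 4)
  s <- multiscale_sample(g, 1)
  p1 <- mgrl_forward(s, params)
  p2 <- mgrl_forward(s, params)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-9)

  # relabeling the fine-scale ROIs (rows+columns of X and A, rows of W0)
  perm <- withr::with_seed(5, sample(12))
  P <- diag(12)[perm, ]
  s2 <- s
  s2$graphs$fine$X <- P %*% s$graphs$fine$X %*% t(P)
  s2$graphs$fine$A <- P %*% s$graphs$fine$A %*% t(P)
  params2 <- params
  params2$gcn$fine$W0 <- P %*% params$gcn$fine$W0
  expect_equal(mgrl_forward(s2, params2), p1, tolerance = 1e-9)
})

test_that("batched scoring equals per-sample forward passes", {
  co <- tiny_cohort(n_subjects = 5, seed = 19, fine = 10, coarse = 5, t_n = 25)
  g <- cohort_graphs(co)
  fit <- train_mgrl(g, train_idx = 1:4, val_idx = NULL,
                    config = train_config(epochs = 2, seed = 3))
  batch <- predict(fit, g)
  for (i in 1:5) {
    single <- mgrl_forward(multiscale_sample(g, i), fit$params)
    expect_equal(unname(batch[i, ]), unname(single), tolerance = 1e-12)
  }
})

test_that("single-scale variants use the narrower head", {
  co <- tiny_cohort(n_subjects = 8, seed = 23, fine = 10, coarse = 5, t_n = 25)
  g <- cohort_graphs(co)
  fit <- train_mgrl(g, train_idx = 1:6, val_idx = 7:8,
                    config = train_config(epochs = 2, seed = 1), scales = "fine")
  dims <- vapply(fit$params$head, function(l) ncol(l$W), numeric(1))
  expect_equal(dims, c(64, 16, 8, 2))
  expect_equal(nrow(fit$params$head[[1]]$W), 64)
  fit2 <- train_mgrl(g, train_idx = 1:6, val_idx = 7:8,
                     config = train_config(epochs = 2, seed = 1))
  dims2 <- vapply(fit2$params$head, function(l) ncol(l$W), numeric(1))
  expect_equal(dims2, c(128, 32, 16, 2))
})

test_that("training reduces the loss on a learnable cohort", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 40, n_timepoints = 60, fine_rois = 20, coarse_rois = 10,
    effect_edge_fraction = 0.25, effect_size = 0.8, seed = 29
  ))
  g <- cohort_graphs(co)
  fit <- train_mgrl(g, train_idx = 1:32, val_idx = 33:36,
                    config = train_config(seed = 7))
  expect_lt(mean(tail(fit$loss, 10)), mean(head(fit$loss, 10)))
  expect_true(all(is.finite(fit$loss)))
  train_acc <- mean((predict(fit, g, idx = 1:32)[, 2] > 0.5) ==
                      (co$label[1:32] == 1))
  expect_gte(train_acc, 0.95)
})
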