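test_that("graph convolution matches hand computations and the loop oracle", {
  H <- matrix(c(2, 0, 1, 3), 2, 2)
  expect_equal(graphConv(H, diag(2), diag(2)), H)

  S <- matrix(0.5, 2, 2)
  expect_equal(graphConv(diag(2), S, diag(2)), matrix(0.5, 2, 2))

  set.seed(31)
  for (rep in 1:10) {
    n <- 6
    A <- (randomCorrMatrix(n) > 0.2) * 1; diag(A) <- 0
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    S <- normalizeAdjacency(A)
    H <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    expect_equal(graphConv(H, S, W), oracleGraphConv(H, S, W),
                 tolerance = 1e-12)
    expect_equal(graphConv(H, S, W, activation = "linear"),
                 oracleGraphConv(H, S, W, relu = FALSE), tolerance = 1e-12)
  }
  expect_error(graphConv(matrix(0, 3, 2), diag(3), matrix(0, 3, 2)),
               "shape mismatch")
})

test_that("self-attention pooling ranks, masks and restricts correctly", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1

  ## Theta = 0: all scores 0, ties break toward lower node indices
  H <- matrix(rnorm(9), 3, 3)
  pr <- sagPool(H, A, matrix(0, 3, 1), k = 2)
  expect_equal(pr$kept_index, c(1L, 2L))
  expect_equal(pr$scores, rep(0, 3))
  expect_equal(pr$pooled_features, matrix(0, 2, 3), ignore_attr = TRUE)

  ## engineered scores (0.9, -0.2, 0.5): keep nodes 1 and 3
  Hs <- matrix(atanh(c(0.9, -0.2, 0.5)), 3, 1)
  pr <- sagPool(Hs, A, matrix(1, 1, 1), k = 2, Spool = diag(3))
  expect_equal(pr$scores, c(0.9, -0.2, 0.5))
  expect_equal(pr$kept_index, c(1L, 3L))
  expect_equal(pr$pooled_adjacency, oracleSubmatrix(A, c(1, 3)))
  expect_equal(pr$pooled_features, Hs[c(1, 3), , drop = FALSE] * c(0.9, 0.5))

  ## pooled adjacency is always the index-pair extraction of the input
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    A <- (randomCorrMatrix(n) > 0.1) * 1; diag(A) <- 0
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    H <- matrix(rnorm(n * 3), n, 3)
    k <- sample(2:(n - 1), 1)
    pr <- sagPool(H, A, matrix(rnorm(3), 3, 1), k)
    expect_equal(pr$pooled_adjacency, oracleSubmatrix(A, pr$kept_index))
    expect_true(all(diff(pr$kept_index) > 0))
  }
  expect_error(sagPool(H, A, matrix(0, 3, 1), k = n + 5), "exceeds")
})

test_that("forward pass yields proper probabilities; zero model is uniform", {
  n <- 12L
  cfg <- gcnConfig(pool_k = 6L, feature_dims = c(8L, 4L), gnn_out_dim = 5L)
  set.seed(33)
  m <- randomCorrMatrix(n)
  g <- binarize(meanMatrix(list(m)), 0.1)
  phen <- encodePhenotype(40, "F")

  zeroParams <- list(W1 = matrix(0, n, 8), W2 = matrix(0, 8, 4),
                     Theta = matrix(0, 4, 1), Wg = matrix(0, 5, 24),
                     bg = numeric(5), Wp = matrix(0, 2, 3), bp = numeric(2),
                     Wc = matrix(0, 3, 7), bc = numeric(3))
  zm <- new("GCNModel", params = zeroParams, config = unclass(cfg),
            history = data.frame())
  expect_equal(gcnForward(zm, m, g, phen), rep(1 / 3, 3))

  rp <- withr::with_seed(1, lapply(zeroParams, function(p) {
    p + rnorm(length(p)) * 0.3
  }))
  rm_ <- new("GCNModel", params = rp, config = unclass(cfg),
             history = data.frame())
  pr <- gcnForward(rm_, m, g, phen)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))
  expect_identical(pr, gcnForward(rm_, m, g, phen))  # bit-stable
})

test_that("training is deterministic under a fixed seed and learns signal", {
  d <- generateCohort(simSpec(n_regions = 10L, n_per_class = c(12L, 12L),
                              n_timepoints = 80L, seed = 8L))
  co <- d$cohort
  g <- buildBackbone(co)
  cfg <- gcnConfig(pool_k = 5L, feature_dims = c(8L, 4L), gnn_out_dim = 6L,
                   epochs = 25L, seed = 17L)
  m1 <- trainGCN(co, g, cfg)
  m2 <- trainGCN(co, g, cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history$loss, m2@history$loss)
  ## loss decreases over training
  expect_lt(mean(tail(m1@history$loss, 5)), mean(head(m1@history$loss, 5)))

  oneClass <- co[cohortLabels(co) == 1]
  expect_error(trainGCN(oneClass, g, cfg), "single class")
})

test_that("validation-based selection returns the best-epoch parameters", {
  d <- generateCohort(simSpec(n_regions = 10L, n_per_class = c(14L, 14L),
                              n_timepoints = 80L, seed = 12L))
  co <- d$cohort
  idx <- withr::with_seed(2, sample(nSubjects(co)))
  tr <- co[idx[1:20]]; va <- co[idx[21:28]]
  g <- buildBackbone(tr)
  cfg <- gcnConfig(pool_k = 5L, feature_dims = c(8L, 4L), gnn_out_dim = 6L,
                   epochs = 15L, seed = 3L)
  fit <- trainGCN(tr, g, cfg, validation = va)
  pred <- apply(predictGCN(fit, va, g), 1, which.max)
  expect_equal(mean(pred == cohortLabels(va)),
               max(fit@history$val_acc, na.rm = TRUE))
})
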