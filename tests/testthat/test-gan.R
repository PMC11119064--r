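test_that("generator output is tanh(X X^T): symmetric, in (-1,1)", {
  cfg <- smallGanConfig(seed = 1L)
  cfgFull <- c(unclass(cfg), list(n_regions = 2L, n_classes = 2L,
                                  phen_len = 3L))
  ## zero embedding map -> X = 0 -> A = 0
  gz <- list(Wh = matrix(0, 16, 20), bh = numeric(16),
             Wo = matrix(0, 2 * 4, 16), bo = numeric(8))
  mz <- new("GANModel", generator = gz, discriminator = list(),
            config = cfgFull, history = data.frame())
  z <- rep(0.1, 20 - 2 - 3)
  A <- generatorForward(mz, z, c(1, 0), c(0.4, 1, 0))
  expect_equal(A, matrix(0, 2, 2))

  ## X = I2 -> A = diag(tanh(1))
  cfg2 <- c(unclass(smallGanConfig(embed_dim = 2L)),
            list(n_regions = 2L, n_classes = 2L, phen_len = 3L))
  gi <- list(Wh = matrix(0, 16, 20), bh = numeric(16),
             Wo = matrix(0, 4, 16), bo = as.vector(diag(2)))
  mi <- new("GANModel", generator = gi, discriminator = list(),
            config = cfg2, history = data.frame())
  A <- generatorForward(mi, z, c(0, 1), c(0.4, 1, 0))
  expect_equal(A, diag(2) * tanh(1) + 0)
  expect_error(generatorForward(mi, rep(0, 3), c(0, 1), c(0.4, 1, 0)),
               "latent_total")

  ## arbitrary (non-saturating) parameters: exact symmetry, open range;
  ## |X X^T| large enough saturates tanh to 1.0 in double precision
  set.seed(41)
  for (rep in 1:10) {
    gr <- list(Wh = matrix(rnorm(16 * 20, sd = 0.2), 16, 20),
               bh = rnorm(16, sd = 0.2),
               Wo = matrix(rnorm(8 * 16, sd = 0.2), 8, 16),
               bo = rnorm(8, sd = 0.2))
    mr <- new("GANModel", generator = gr, discriminator = list(),
              config = cfgFull, history = data.frame())
    A <- generatorForward(mr, rnorm(15), c(1, 0), runif(3))
    expect_identical(A, t(A))
    expect_true(all(abs(A) < 1))
  }
})

test_that("BrainNetCNN layer forwards match hand computations and loop oracles", {
  M <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(e2eForward(M, c(1, 1), c(1, 1), 0), matrix(2, 2, 2))
  ## indicator row weight: out(i, j) = M(i, 1) for all j
  M3 <- matrix(rnorm(9), 3, 3)
  out <- e2eForward(M3, c(1, 0, 0), c(0, 0, 0), 0)
  expect_equal(out, matrix(rep(M3[, 1], 3), 3, 3))
  expect_equal(e2eForward(matrix(0, 3, 3), rnorm(3), rnorm(3), 1.5),
               matrix(1.5, 3, 3))

  expect_equal(e2nForward(M3, c(1, 1, 1), 0), rowSums(M3))
  expect_equal(e2nForward(M3, c(0, 1, 0), 0), M3[, 2])
  expect_equal(n2gForward(c(3, 6, 9), rep(1 / 3, 3), 0), 6)
  expect_equal(n2gForward(rep(0, 4), rnorm(4), 0.7), 0.7)

  set.seed(42)
  for (rep in 1:10) {
    n <- 8
    M <- matrix(rnorm(n * n), n, n)
    rw <- rnorm(n); cw <- rnorm(n); w <- rnorm(n); b <- rnorm(1)
    expect_equal(e2eForward(M, rw, cw, b), oracleE2E(M, rw, cw, b),
                 tolerance = 1e-12)
    expect_equal(e2nForward(M, w, b), oracleE2N(M, w, b), tolerance = 1e-12)
    v <- rnorm(n)
    expect_equal(n2gForward(v, w, b), oracleN2G(v, w, b), tolerance = 1e-12)
  }
  expect_error(e2eForward(M, rnorm(3), rnorm(8)), "shape mismatch")
})

test_that("discriminator evaluation is deterministic with valid heads", {
  d <- generateCohort(simSpec(n_regions = 8L, n_per_class = c(6L, 6L),
                              n_timepoints = 60L, seed = 14L))
  co <- d$cohort
  m <- untrainedDisc(co, smallGanConfig(epochs = 0L, seed = 2L))
  fc <- fcMatrices(co)[, , 1]
  phen <- phenotypeMatrix(co)[, 1]
  o1 <- discriminatorForward(m, fc, phen)
  o2 <- discriminatorForward(m, fc, phen)
  expect_identical(o1, o2)
  expect_gt(o1$validity, 0); expect_lt(o1$validity, 1)
  expect_equal(sum(o1$probs), 1, tolerance = 1e-6)
  expect_error(discriminatorForward(m, diag(5), phen), "n_regions")

  ## an untrained model predicts at chance on a balanced cohort
  pr <- predictDiscriminator(m, co)
  expect_equal(dim(pr), c(12L, 2L))
  acc <- mean(apply(pr, 1, which.max) == cohortLabels(co))
  expect_gte(acc, 0.2); expect_lte(acc, 0.8)
})

test_that("adversarial training is seed-deterministic and aborts cleanly", {
  d <- generateCohort(simSpec(n_regions = 8L, n_per_class = c(6L, 6L),
                              n_timepoints = 60L, seed = 15L))
  co <- d$cohort
  cfg <- smallGanConfig(epochs = 3L, seed = 6L)
  m1 <- trainGAN(co, cfg)
  m2 <- trainGAN(co, cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@discriminator$params, m2@discriminator$params)
  expect_identical(m1@generator, m2@generator)
  expect_error(trainGAN(co[cohortLabels(co) == 1], cfg), "single class")

  b1 <- trainBrainNetCNN(co, cfg)
  b2 <- trainBrainNetCNN(co, cfg)
  expect_identical(b1@discriminator$params, b2@discriminator$params)
  expect_length(b1@generator, 0)
})

test_that("generated samples are reproducible, symmetric and in range", {
  d <- generateCohort(simSpec(n_regions = 8L, n_per_class = c(6L, 6L),
                              n_timepoints = 60L, seed = 16L))
  co <- d$cohort
  m <- trainGAN(co, smallGanConfig(epochs = 2L, seed = 4L))

  s0 <- generateSamples(m, 0L, co, seed = 1)
  expect_equal(dim(s0$matrices)[3], 0L)

  s1 <- generateSamples(m, 12L, co, seed = 5)
  s2 <- generateSamples(m, 12L, co, seed = 5)
  expect_identical(s1$matrices, s2$matrices)
  expect_identical(s1$labels, s2$labels)
  for (i in 1:12) {
    A <- s1$matrices[, , i]
    expect_identical(A, t(A))
    expect_true(all(abs(A) < 1))
  }
})

test_that("the conditioned generator avoids mode collapse on a planted effect", {
  ## scaled-down diagnostic: one seed at the default epoch budget
  d <- generateCohort(simSpec(n_regions = 20L, n_per_class = c(30L, 30L),
                              seed = 77L))
  co <- d$cohort
  m <- trainGAN(co, ganConfig(epochs = 300L, seed = 5L))
  s1 <- generateSamples(m, 100L, co, seed = 9, labels = rep(1L, 100))
  s2 <- generateSamples(m, 100L, co, seed = 10, labels = rep(2L, 100))
  y <- cohortLabels(co)
  r1 <- apply(fcMatrices(co[y == 1]), c(1, 2), mean)
  r2 <- apply(fcMatrices(co[y == 2]), c(1, 2), mean)
  g1 <- apply(s1$matrices, c(1, 2), mean)
  g2 <- apply(s2$matrices, c(1, 2), mean)
  fro <- function(a, b) sqrt(sum((a - b)^2))

  ## dispersion: samples are not identical copies
  pd <- mean(apply(utils::combn(30, 2), 2, function(ij) {
    fro(s1$matrices[, , ij[1]], s1$matrices[, , ij[2]])
  }))
  expect_gt(pd, 0)
  ## each class's generated mean sits closer to its own real class mean
  expect_lt(fro(g1, r1), fro(g1, r2))
  expect_lt(fro(g2, r2), fro(g2, r1))
})

test_that("hand-derived discriminator gradients match finite differences", {
  cfg <- ganConfig(ece_maps = 3L, ecn_filters = 4L, ncg_filters = 5L,
                   disc_dense = 6L, phen_dense = 3L, joint_dense = 4L,
                   dropout = 0, seed = 1L)
  n <- 5L; B <- 3L; p <- 3L; C <- 2L
  set.seed(61)
  di <- fcnet:::.discInit(n, p, C, cfg)
  M <- array(rnorm(n * n * B), c(n, n, B))
  for (b in 1:B) M[, , b] <- (M[, , b] + t(M[, , b])) / 2
  Ph <- matrix(runif(p * B), p, B)
  vT <- c(1, 0, 1); y <- c(1L, 2L, 2L)
  Yoh <- matrix(0, C, B); Yoh[cbind(y, 1:B)] <- 1
  lossFn <- function(pp) {
    fw <- fcnet:::.discForward(pp, di$stats, M, Ph, cfg, training = TRUE)
    -mean(vT * log(fw$validity) + (1 - vT) * log(1 - fw$validity)) -
      sum(log(colSums(fw$probs * Yoh))) / B
  }
  fw <- fcnet:::.discForward(di$params, di$stats, M, Ph, cfg, training = TRUE)
  dv <- matrix((fw$validity - vT) / B, 1)
  dc <- (fw$probs - Yoh) / B
  bw <- fcnet:::.discBackward(di$params, cfg, fw, dv, dc,
                              wantInputGrad = TRUE)
  eps <- 1e-6
  for (nm in names(di$params)) {
    g <- bw$grads[[nm]]
    for (k in sample(length(g), min(3, length(g)))) {
      pp <- di$params
      pp[[nm]][k] <- pp[[nm]][k] + eps; up <- lossFn(pp)
      pp[[nm]][k] <- pp[[nm]][k] - 2 * eps; dn <- lossFn(pp)
      expect_equal(g[k], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
  }
  ## gradient w.r.t. the input matrices (drives the generator update)
  for (k in sample(n * n * B, 6)) {
    MM <- M; MM[k] <- MM[k] + eps
    fw1 <- fcnet:::.discForward(di$params, di$stats, MM, Ph, cfg,
                                training = TRUE)
    l1 <- -mean(vT * log(fw1$validity) + (1 - vT) * log(1 - fw1$validity)) -
      sum(log(colSums(fw1$probs * Yoh))) / B
    MM[k] <- MM[k] - 2 * eps
    fw2 <- fcnet:::.discForward(di$params, di$stats, MM, Ph, cfg,
                                training = TRUE)
    l2 <- -mean(vT * log(fw2$validity) + (1 - vT) * log(1 - fw2$validity)) -
      sum(log(colSums(fw2$probs * Yoh))) / B
    expect_equal(bw$dM[k], (l1 - l2) / (2 * eps), tolerance = 1e-5)
  }
})
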