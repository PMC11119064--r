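test_that("meanMatrix is the per-entry arithmetic mean with zero diagonal", {
  m <- randomCorrMatrix(5)
  single <- meanMatrix(list(m))
  expect_equal(unname(single[upper.tri(single)]), m[upper.tri(m)])
  expect_equal(diag(single), rep(0, 5), ignore_attr = TRUE)

  a <- diag(3); a[upper.tri(a)] <- 0.2; a <- a + t(a) - diag(diag(a))
  b <- diag(3); b[upper.tri(b)] <- 0.4; b <- b + t(b) - diag(diag(b))
  expect_equal(meanMatrix(list(a, b))[1, 2], 0.3)

  set.seed(4)
  mats <- replicate(10, randomCorrMatrix(6), simplify = FALSE)
  mm <- meanMatrix(mats)
  for (i in 1:6) for (j in 1:6) {
    ref <- if (i == j) 0 else mean(vapply(mats, function(x) x[i, j],
                                          numeric(1)))
    expect_equal(mm[i, j], ref)
  }
  expect_error(meanMatrix(list()), "non-empty")
})

test_that("retention curve counts positive connections only, strictly above tau", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.1; m[1, 3] <- 0.2; m[1, 4] <- 0.3
  m[2, 3] <- -0.5; m[2, 4] <- -0.2; m[3, 4] <- 0
  m <- m + t(m)
  rc <- retentionCurve(m, c(0, 0.15, 0.35))
  expect_equal(rc$retained, c(1, 2 / 3, 0))
  expect_error(retentionCurve(-abs(randomCorrMatrix(4)) + 2 * diag(4) - diag(4),
                              c(0, 0.1)), "no positive")
  expect_error(retentionCurve(m, c(0.2, 0.1)), "ascending")
})

test_that("retention curves are non-increasing on random matrices", {
  set.seed(11)
  for (rep in 1:20) {
    m <- meanMatrix(replicate(5, randomCorrMatrix(8), simplify = FALSE))
    rc <- retentionCurve(m, seq(0, max(m) * 0.99, length.out = 25))
    expect_true(all(diff(rc$retained) <= 1e-12))
    expect_equal(rc$retained[1], 1)
  }
})

test_that("elbow selection maximizes chord distance; degenerate curves warn", {
  tau <- seq(0, 0.5, by = 0.01)
  curve <- data.frame(tau = tau, retained = exp(-10 * tau))
  expect_equal(selectElbow(curve), oracleElbow(tau, exp(-10 * tau)))

  ## piecewise-linear curve with a single breakpoint at tau = 0.2
  pw <- ifelse(tau <= 0.2, 1 - 4 * tau, 0.2 - 0.5 * (tau - 0.2))
  expect_equal(selectElbow(data.frame(tau = tau, retained = pw)), 0.2)

  expect_warning(
    out <- selectElbow(data.frame(tau = tau, retained = 1 - tau)),
    "no elbow")
  expect_equal(out, 0)
  expect_error(selectElbow(data.frame(tau = 1:2, retained = c(1, 0))),
               "3 grid points")
})

test_that("binarize produces the normalized self-looped operator", {
  ## 2 nodes, one edge: degrees with self-loops are 2, S = 1/2 everywhere
  m <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  g <- binarize(m, 0.15)
  expect_equal(g@adjacency, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(g@normalized, matrix(0.5, 2, 2))

  ## tau above the maximum: self-loops only, S = I (with a warning)
  expect_warning(g0 <- binarize(m, 0.5), "empty edge set")
  expect_equal(g0@normalized, diag(2))

  ## 3-node path 1-2-3: self-looped degrees 2, 3, 2
  m3 <- matrix(0, 3, 3); m3[1, 2] <- m3[2, 1] <- 0.3
  m3[2, 3] <- m3[3, 2] <- 0.3
  g3 <- binarize(m3, 0.15)
  S <- g3@normalized
  expect_equal(S[1, 1], 1 / 2)
  expect_equal(S[1, 2], 1 / sqrt(6))
  expect_equal(S[2, 2], 1 / 3)
  expect_equal(S[1, 3], 0)
  expect_equal(S[3, 3], 1 / 2)
})

test_that("normalized operators are symmetric, nonnegative, spectral radius <= 1", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(5:50, 1)
    m <- meanMatrix(replicate(4, randomCorrMatrix(n), simplify = FALSE))
    tau <- stats::quantile(m[upper.tri(m)], 0.7)
    g <- binarize(m, max(tau, 0))
    S <- g@normalized
    expect_equal(S, t(S))
    expect_gte(min(S), 0)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-9)
  }
})

test_that("buildBackbone supports a user-supplied tau override", {
  co <- tinyCohort()
  g <- buildBackbone(co, grid = seq(0, 0.4, 0.05), tau = 0.25)
  expect_equal(g@tau, 0.25)
  expect_s4_class(g, "BackboneGraph")
  expect_true(!is.null(attr(g, "curve")))
})
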