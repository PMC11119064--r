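test_that("splits follow the 10% holdout + 5-fold protocol deterministically", {
  co <- labelsOnlyCohort(rep(c("control", "patient"), each = 50))
  plan <- splitPlan(seed = 9L)
  sp <- makeSplits(co, plan)
  expect_length(sp$test, 10L)
  expect_length(sp$folds, 5L)
  rest <- setdiff(1:100, sp$test)
  allVal <- integer(0)
  for (f in sp$folds) {
    expect_length(f$validation, 18L)
    expect_length(f$train, 72L)
    expect_length(intersect(f$validation, sp$test), 0L)
    expect_length(intersect(f$train, f$validation), 0L)
    allVal <- c(allVal, f$validation)
  }
  expect_setequal(allVal, rest)          # each subject in exactly one fold
  expect_length(allVal, length(rest))

  sp2 <- makeSplits(co, plan)
  expect_identical(sp, sp2)

  ## stratified: fold class ratios within one subject of 50%
  y <- cohortLabels(co)
  for (f in sp$folds) {
    expect_lte(abs(sum(y[f$validation] == 1) - 9), 1)
  }
})

test_that("metric panel matches direct formula evaluation", {
  ## binary: TP=3, FP=1, FN=1, TN=5 for the positive (patient) class
  yt <- c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1)
  yp <- c(2, 2, 2, 1, 2, 1, 1, 1, 1, 1)
  r <- computeMetrics(yt, yp, n_classes = 2)
  expect_equal(r@metrics[["accuracy"]], 0.8)
  expect_equal(r@metrics[["precision"]], 0.75)
  expect_equal(r@metrics[["recall"]], 0.75)
  expect_equal(r@metrics[["specificity"]], 5 / 6)
  expect_equal(r@metrics[["f1"]], 0.75)

  ## perfect prediction, one-hot scores
  yt <- rep(1:3, each = 2); yp <- yt
  sc <- matrix(0, 6, 3); sc[cbind(1:6, yt)] <- 1
  r <- computeMetrics(yt, yp, sc, 3)
  expect_equal(unname(r@metrics), rep(1, 6))

  ## per-class counting oracle on random predictions
  set.seed(51)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    n <- sample(20:200, 1)
    yt <- sample(k, n, replace = TRUE)
    yp <- sample(k, n, replace = TRUE)
    r <- computeMetrics(yt, yp, n_classes = k)
    for (cl in seq_len(k)) {
      o <- oraclePerClass(yt, yp, cl)
      expect_equal(unname(r@perClass[cl, c("precision", "recall",
                                           "specificity")]),
                   unname(o))
    }
  }
})

test_that("macro AUC equals the rank statistic and handles scores sensibly", {
  yt <- c(1, 1, 2, 2)
  sc <- cbind(c(0.9, 0.6, 0.3, 0.2), c(0.1, 0.4, 0.7, 0.8))
  r <- computeMetrics(yt, c(1, 1, 2, 2), sc, 2)
  expect_equal(r@metrics[["auc"]], 1)
  ## one discordant pair among 4: AUC = 3/4
  sc2 <- cbind(c(0.9, 0.3, 0.6, 0.2), c(0.1, 0.7, 0.4, 0.8))
  r2 <- computeMetrics(yt, c(1, 2, 1, 2), sc2, 2)
  expect_equal(r2@metrics[["auc"]], 0.75)
})

test_that("exact binomial tail matches enumeration and is monotone", {
  expect_equal(binomialSignificance(10, 10, 0.5), 0.5^10)
  expect_equal(binomialSignificance(0, 10, 0.5), 1)
  expect_equal(binomialSignificance(15, 20, 0.5), oracleBinomTail(15, 20, 0.5))
  for (n in c(5, 13, 25)) {
    ps <- vapply(0:n, function(k) binomialSignificance(k, n, 0.5), numeric(1))
    ref <- vapply(0:n, function(k) oracleBinomTail(k, n, 0.5), numeric(1))
    expect_equal(ps, ref, tolerance = 1e-12)
    expect_true(all(diff(ps) < 0))
  }
  expect_equal(binomialSignificance(7, 10, 1 / 3),
               oracleBinomTail(7, 10, 1 / 3))
  expect_error(binomialSignificance(3, 0), "positive")
})

test_that("rank-sum comparison: exact enumeration, ties, approximation", {
  expect_equal(wilcoxonCompare(c(4, 5, 6), c(1, 2, 3)), 0.05)
  expect_warning(p <- wilcoxonCompare(c(1, 1), c(1, 1)), "degenerate")
  expect_equal(p, 1)
  a <- c(2, 2, 3); b <- c(1, 2, 4)      # ties across groups
  expect_equal(wilcoxonCompare(a, b), oracleRankSumP(a, b))
  set.seed(52)
  for (rep in 1:10) {
    a <- round(runif(5), 2); b <- round(runif(5), 2)
    expect_equal(wilcoxonCompare(a, b), oracleRankSumP(a, b))
  }
  ## tie-free exact path agrees with the classical distribution
  a <- c(0.71, 0.80, 0.62, 0.55); b <- c(0.50, 0.49, 0.63, 0.41)
  expect_equal(wilcoxonCompare(a, b),
               stats::wilcox.test(a, b, alternative = "greater",
                                  exact = TRUE)$p.value)
  ## large samples: normal approximation close to the exact R implementation
  set.seed(53)
  a <- rnorm(10, 0.5); b <- rnorm(10)
  expect_equal(wilcoxonCompare(a, b),
               stats::wilcox.test(a, b, alternative = "greater",
                                  correct = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-8)
})

test_that("benchmark harness trains, selects on validation and reports", {
  d <- generateCohort(simSpec(n_regions = 10L, n_per_class = c(14L, 14L),
                              n_timepoints = 80L, seed = 19L))
  co <- d$cohort
  plan <- splitPlan(test_fraction = 0.1, n_folds = 3L, seed = 7L)
  models <- list(
    gcn = list(type = "gcn",
               config = gcnConfig(pool_k = 5L, feature_dims = c(8L, 4L),
                                  gnn_out_dim = 6L, epochs = 15L, seed = 2L)),
    bnc = list(type = "bnc",
               config = smallGanConfig(epochs = 5L, seed = 2L)))
  out <- runBenchmark(co, models, plan)
  expect_named(out$reports, c("gcn", "bnc"))
  for (r in out$reports) {
    expect_s4_class(r, "EvalReport")
    expect_length(r@foldAccuracies, 3L)
    expect_true(r@significance$binomial_p >= 0 &&
                r@significance$binomial_p <= 1)
  }
  expect_false(is.na(out$wilcoxon["gcn", "bnc"]))
  expect_equal(nrow(out$ranking), 2L)
  expect_true(!is.unsorted(out$ranking$test_accuracy))

  ## single model: no pairwise tests, report still valid
  out1 <- runBenchmark(co, models["gcn"], plan)
  expect_true(all(is.na(out1$wilcoxon)))
  expect_s4_class(out1$reports$gcn, "EvalReport")
})
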