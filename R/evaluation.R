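#' Holdout + cross-validation split plan
#'
#' 10\% of the data is held out for testing; the remainder is split into
#' 5 folds, each serving once as validation. Stratified by class by default.
#'
#' @param test_fraction fraction held out for the test set (default 0.10)
#' @param n_folds number of cross-validation folds (default 5)
#' @param stratified stratify both splits by class (default TRUE)
#' @param seed integer seed
#' @return list of class "fcnet_splitplan"
#' @export
splitPlan <- function(test_fraction = 0.10, n_folds = 5L, stratified = TRUE,
                      seed = 1L) {
  plan <- list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
               stratified = isTRUE(stratified), seed = as.integer(seed))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  class(plan) <- "fcnet_splitplan"
  plan
}

# Deal indices of one class round-robin into k folds after shuffling.
.dealFolds <- function(idx, k) {
  split(idx, rep_len(seq_len(k), length(idx)))
}

#' Make holdout and cross-validation index sets
#'
#' Deterministic under the plan's seed. The test indices are disjoint from
#' every fold; each remaining subject appears in exactly one validation fold.
#'
#' @param cohort an \linkS4class{FCCohort}
#' @param plan a \code{\link{splitPlan}}
#' @return list: \code{test} (integer indices) and \code{folds}, a list of
#'   \code{list(train=, validation=)} index pairs
#' @export
makeSplits <- function(cohort, plan = splitPlan()) {
  y <- cohortLabels(cohort)
  ns <- length(y)
  withSeed(deriveSeed(plan$seed, "split"), {
    if (plan$stratified) {
      test <- integer(0)
      for (k in sort(unique(y))) {
        idx <- sample(which(y == k))
        nTest <- round(plan$test_fraction * length(idx))
        test <- c(test, idx[seq_len(nTest)])
      }
      test <- sort(test)
      rest <- setdiff(seq_len(ns), test)
      ## deal each class round-robin across folds
      foldsIdx <- vector("list", plan$n_folds)
      for (k in sort(unique(y))) {
        idx <- sample(rest[y[rest] == k])
        dealt <- .dealFolds(idx, plan$n_folds)
        for (f in seq_along(dealt)) {
          foldsIdx[[f]] <- c(foldsIdx[[f]], dealt[[f]])
        }
      }
    } else {
      perm <- sample.int(ns)
      nTest <- round(plan$test_fraction * ns)
      test <- sort(perm[seq_len(nTest)])
      rest <- perm[(nTest + 1L):ns]
      foldsIdx <- .dealFolds(rest, plan$n_folds)
    }
    folds <- lapply(seq_len(plan$n_folds), function(f) {
      val <- sort(foldsIdx[[f]])
      train <- sort(unlist(foldsIdx[-f]))
      yt <- y[train]
      if (length(unique(yt)) < length(unique(y))) {
        msg <- sprintf("fold %d: a class is absent from training", f)
        if (plan$stratified) stop(msg) else warning(msg)
      }
      list(train = train, validation = val)
    })
    list(test = test, folds = folds)
  })
}

#' One-sided exact binomial significance test for classifier accuracy
#'
#' Models the classifier's correct/incorrect outcomes as a Bernoulli process
#' and returns the exact upper tail P(X >= n_correct | n_total, p0) with
#' X ~ Binomial(n_total, p0): the probability that a chance-level classifier
#' does at least as well.
#'
#' @param n_correct number of correctly classified test subjects
#' @param n_total test-set size
#' @param p0 chance level; 0.5 for binary, typically 1/n_classes otherwise
#' @return the one-sided p-value
#' @export
binomialSignificance <- function(n_correct, n_total, p0 = 0.5) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) {
    stop("n_correct must be in [0, n_total]")
  }
  stats::pbinom(n_correct - 1, n_total, p0, lower.tail = FALSE)
}

#' One-sided Wilcoxon rank-sum comparison of fold accuracies
#'
#' Tests H1: samples in \code{a} tend to be larger than those in \code{b}
#' (the proposed model generalizes better). For combined n <= 12 the exact
#' permutation distribution of the rank sum is enumerated with tie-corrected
#' mid-ranks; larger samples use the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b numeric vectors (e.g. the 5 cross-validation accuracies of two
#'   models)
#' @return one-sided p-value for H1: a > b
#' @export
wilcoxonCompare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    warning("degenerate data: all values identical across both groups")
    return(1)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))                    # mid-ranks under ties
  W <- sum(r[seq_len(na)])
  if (n <= 12L) {
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    mean(sums >= W)
  } else {
    ties <- table(r)
    tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
    mu <- na * (n + 1) / 2
    sig <- sqrt(na * nb / 12 * ((n + 1) - tieCorr))
    stats::pnorm((W - mu - 0.5) / sig, lower.tail = FALSE)
  }
}

#' Classification metric panel (macro one-vs-rest)
#'
#' Accuracy plus per-class one-vs-rest precision, recall (sensitivity),
#' specificity and F1 with unweighted macro averaging, and macro OvR AUC
#' computed from the rank statistic of the per-class probability scores.
#' Per-class metrics with a zero denominator are dropped from the macro mean
#' with a note (mirroring "-" entries in published tables). In the binary
#' case the metrics reduce to the standard definitions with the designated
#' positive class (the last, non-control, label by convention).
#'
#' @param y_true integer class labels (1..n_classes)
#' @param y_pred integer predicted labels
#' @param y_scores matrix of per-class probabilities (subjects x classes);
#'   optional, required for AUC
#' @param n_classes number of classes
#' @param foldAccuracies optional per-fold accuracies to attach
#' @return an \linkS4class{EvalReport}
#' @export
computeMetrics <- function(y_true, y_pred, y_scores = NULL,
                           n_classes = max(y_true),
                           foldAccuracies = numeric(0)) {
  stopifnot(length(y_true) == length(y_pred))
  ns <- length(y_true)
  acc <- mean(y_true == y_pred)
  per <- matrix(NA_real_, n_classes, 5,
                dimnames = list(paste0("class", seq_len(n_classes)),
                                c("precision", "recall", "specificity",
                                  "f1", "auc")))
  notes <- character(0)
  for (k in seq_len(n_classes)) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    tn <- sum(y_true != k & y_pred != k)
    per[k, "precision"] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per[k, "recall"] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    per[k, "specificity"] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    pr <- per[k, "precision"]; rc <- per[k, "recall"]
    per[k, "f1"] <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0) {
      2 * pr * rc / (pr + rc)
    } else NA_real_
    if (!is.null(y_scores)) {
      pos <- y_scores[y_true == k, k]
      neg <- y_scores[y_true != k, k]
      per[k, "auc"] <- if (length(pos) && length(neg)) {
        ## Mann-Whitney rank statistic; ties get half credit
        r <- rank(c(pos, neg))
        (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
          (length(pos) * length(neg))
      } else NA_real_
    }
    if (anyNA(per[k, ])) {
      notes <- c(notes, sprintf(
        "class %d: undefined metric(s) dropped from macro mean", k))
    }
  }
  ## binary: standard definitions for the designated positive class (the
  ## last, non-control label); multiclass: unweighted macro mean, dropping
  ## undefined per-class values
  macro <- function(col) {
    if (n_classes == 2L) per[2L, col] else mean(per[, col], na.rm = TRUE)
  }
  metrics <- c(accuracy = acc, precision = macro("precision"),
               recall = macro("recall"), specificity = macro("specificity"),
               f1 = macro("f1"),
               auc = if (is.null(y_scores)) NA_real_ else macro("auc"))
  new("EvalReport", metrics = metrics, perClass = per,
      foldAccuracies = as.numeric(foldAccuracies),
      significance = list(),
      details = list(confusion = table(true = factor(y_true,
                                                     seq_len(n_classes)),
                                       pred = factor(y_pred,
                                                     seq_len(n_classes))),
                     notes = notes))
}

#' Cross-validated benchmark of model specifications
#'
#' For each model: train once per fold (the backbone graph, where needed, is
#' built from the fold's training subjects only), select the fold model with
#' the best validation accuracy (for the GAN, validity accuracy nearest 0.5
#' breaks ties), evaluate the selected model once on the held-out test set,
#' and report the metric panel, the per-model exact binomial p-value against
#' chance and pairwise one-sided Wilcoxon comparisons of fold accuracies.
#'
#' @param cohort an \linkS4class{FCCohort}
#' @param models named list of model specs, each
#'   \code{list(type = "gcn"|"gan"|"bnc", config = ..., grid = , tau = )}
#' @param plan a \code{\link{splitPlan}}
#' @param p0 chance level for the binomial test; default 1/n_classes
#' @return list: \code{reports} (named \linkS4class{EvalReport}s),
#'   \code{wilcoxon} (matrix of pairwise one-sided p-values, row > column),
#'   \code{ranking} (data.frame sorted worst to best test accuracy)
#' @export
runBenchmark <- function(cohort, models, plan = splitPlan(), p0 = NULL) {
  splits <- makeSplits(cohort, plan)
  testC <- cohort[splits$test]
  yTest <- cohortLabels(testC)
  nClasses <- length(labelNames(cohort))
  if (is.null(p0)) p0 <- 1 / nClasses
  reports <- list()

  for (nm in names(models)) {
    spec <- models[[nm]]
    foldAcc <- numeric(0)
    bestVal <- -Inf; bestFit <- NULL
    for (f in seq_along(splits$folds)) {
      tr <- cohort[splits$folds[[f]]$train]
      va <- cohort[splits$folds[[f]]$validation]
      if (spec$type == "gcn") {
        graph <- buildBackbone(tr,
                               grid = spec$grid %||% seq(0, 0.5, 0.01),
                               tau = spec$tau)
        cfg <- spec$config %||% gcnConfig()
        cfg$seed <- deriveSeed(cfg$seed, "fold", f)
        fit <- trainGCN(tr, graph, cfg, validation = va)
        vacc <- max(fit@history$val_acc, na.rm = TRUE)
        fitObj <- list(model = fit, graph = graph)
      } else {
        cfg <- spec$config %||% ganConfig()
        cfg$seed <- deriveSeed(cfg$seed, "fold", f)
        fit <- if (spec$type == "gan") trainGAN(tr, cfg, validation = va)
               else trainBrainNetCNN(tr, cfg, validation = va)
        vacc <- max(fit@history$val_acc, na.rm = TRUE)
        fitObj <- list(model = fit)
      }
      foldAcc <- c(foldAcc, vacc)
      if (vacc > bestVal) { bestVal <- vacc; bestFit <- fitObj }
    }
    scores <- if (!is.null(bestFit$graph)) {
      predictGCN(bestFit$model, testC, bestFit$graph)
    } else {
      predictDiscriminator(bestFit$model, testC)
    }
    pred <- apply(scores, 1L, which.max)
    rep_ <- computeMetrics(yTest, pred, scores, nClasses, foldAcc)
    rep_@significance <- list(
      binomial_p = binomialSignificance(sum(pred == yTest), length(yTest),
                                        p0))
    reports[[nm]] <- rep_
  }

  wil <- matrix(NA_real_, length(models), length(models),
                dimnames = list(names(models), names(models)))
  if (length(models) > 1L) {
    for (i in names(models)) for (j in names(models)) {
      if (i != j) {
        wil[i, j] <- wilcoxonCompare(reports[[i]]@foldAccuracies,
                                     reports[[j]]@foldAccuracies)
      }
    }
  }
  ranking <- data.frame(
    model = names(reports),
    test_accuracy = vapply(reports, function(r) r@metrics[["accuracy"]],
                           numeric(1)))
  ranking <- ranking[order(ranking$test_accuracy), , drop = FALSE]
  list(reports = reports, wilcoxon = wil, ranking = ranking)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
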