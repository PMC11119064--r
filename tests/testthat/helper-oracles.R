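# Independent brute-force reference implementations ("oracles") and small
# fixture builders. These deliberately use explicit loops and elementary
# formulas so they share no code path with the package implementation.

oracleGraphConv <- function(H, S, W, relu = TRUE) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    agg <- rep(0, ncol(H))
    for (j in seq_len(n)) agg <- agg + S[i, j] * H[j, ]
    out[i, ] <- as.vector(agg %*% W)
  }
  if (relu) out[out < 0] <- 0
  out
}

oracleSubmatrix <- function(A, idx) {
  k <- length(idx)
  out <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) out[a, b] <- A[idx[a], idx[b]]
  out
}

oracleE2E <- function(M, rw, cw, bias) {
  n <- nrow(M)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- bias
    for (k in seq_len(n)) s <- s + rw[k] * M[i, k] + cw[k] * M[k, j]
    out[i, j] <- s
  }
  out
}

oracleE2N <- function(M, w, bias) {
  n <- nrow(M)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- bias
    for (j in seq_len(n)) s <- s + w[j] * M[i, j]
    out[i] <- s
  }
  out
}

oracleN2G <- function(v, w, bias) {
  s <- bias
  for (i in seq_along(v)) s <- s + w[i] * v[i]
  s
}

oracleBinomTail <- function(k, n, p0) {
  if (k <= 0) return(1)
  s <- 0
  for (j in k:n) s <- s + choose(n, j) * p0^j * (1 - p0)^(n - j)
  s
}

oracleRankSumP <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  combs <- utils::combn(n, na)
  hits <- 0
  for (cidx in seq_len(ncol(combs))) {
    if (sum(r[combs[, cidx]]) >= W) hits <- hits + 1
  }
  hits / ncol(combs)
}

oracleElbow <- function(tau, retained) {
  xs <- (tau - tau[1]) / (tau[length(tau)] - tau[1])
  ys <- (retained - min(retained)) /
    max(max(retained) - min(retained), .Machine$double.eps)
  best <- -1; bestTau <- NA
  x0 <- xs[1]; y0 <- ys[1]; x1 <- xs[length(xs)]; y1 <- ys[length(ys)]
  den <- sqrt((y1 - y0)^2 + (x1 - x0)^2)
  for (i in seq_along(tau)) {
    d <- abs((y1 - y0) * xs[i] - (x1 - x0) * ys[i] + x1 * y0 - y1 * x0) / den
    if (d > best + 1e-15) { best <- d; bestTau <- tau[i] }
  }
  bestTau
}

oraclePerClass <- function(y_true, y_pred, k) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == k && y_pred[i] == k) tp <- tp + 1
    if (y_true[i] != k && y_pred[i] == k) fp <- fp + 1
    if (y_true[i] == k && y_pred[i] != k) fn <- fn + 1
    if (y_true[i] != k && y_pred[i] != k) tn <- tn + 1
  }
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA)
}

# Random symmetric correlation-like matrix with unit diagonal.
randomCorrMatrix <- function(n, t = 4 * n) {
  stats::cor(matrix(stats::rnorm(t * n), t, n))
}

# Small hand-assembled cohort for IO tests.
tinyCohort <- function(withSite = FALSE) {
  m1 <- matrix(c(1, .2, .3, -.1,
                 .2, 1, .4, .0,
                 .3, .4, 1, .5,
                 -.1, .0, .5, 1), 4, 4)
  m2 <- matrix(c(1, -.2, .1, .6,
                 -.2, 1, .25, .3,
                 .1, .25, 1, -.4,
                 .6, .3, -.4, 1), 4, 4)
  ph <- data.frame(subject_id = c("sub01", "sub02"), age = c(34.5, 61),
                   sex = c("F", "M"), label = c("control", "patient"),
                   stringsAsFactors = FALSE)
  if (withSite) ph$site <- c("siteB", "siteA")
  FCCohort(list(m1, m2), ph, provenance = "test fixture")
}

# Cheap valid cohort (identity matrices) for split-protocol tests.
labelsOnlyCohort <- function(labels) {
  n <- length(labels)
  mats <- replicate(n, diag(6), simplify = FALSE)
  ph <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                   age = rep(40, n), sex = rep(c("F", "M"), length.out = n),
                   label = labels, stringsAsFactors = FALSE)
  FCCohort(mats, ph)
}

# Zero-epoch (randomly initialized) BrainNetCNN-family model on a cohort.
untrainedDisc <- function(cohort, cfg = NULL) {
  if (is.null(cfg)) cfg <- ganConfig(epochs = 0L, seed = 1L)
  trainBrainNetCNN(cohort, cfg)
}

smallGanConfig <- function(...) {
  defaults <- list(latent_total = 20L, embed_dim = 4L, ece_maps = 4L,
                   ecn_filters = 8L, ncg_filters = 8L, disc_dense = 8L,
                   phen_dense = 4L, joint_dense = 6L, gen_hidden = 16L,
                   batch_size = 8L)
  do.call(ganConfig, utils::modifyList(defaults, list(...)))
}
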