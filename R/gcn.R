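#' Configuration for the spectral GCN classifier
#'
#' Defaults follow the published architecture: two convolution layers with
#' output widths 25 and 10, self-attention pooling down to 10 nodes, a
#' length-15 projection of the flattened graph representation, a length-2
#' projection of the phenotype encoding, a softmax head, and Adam with
#' learning rate 0.01. Epochs, batch size and initialization are exposed
#' (the publication leaves them unstated).
#'
#' @param feature_dims output widths of the two convolution layers
#' @param pool_k nodes kept by the pooling layer
#' @param gnn_out_dim width of the graph-representation projection
#' @param phen_out_dim width of the phenotype projection
#' @param learning_rate Adam learning rate
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param class_weights use inverse-frequency class weights in the loss
#' @param seed integer seed controlling initialization and shuffling
#' @return list of class "fcnet_gcnconfig"
#' @export
gcnConfig <- function(feature_dims = c(25L, 10L), pool_k = 10L,
                      gnn_out_dim = 15L, phen_out_dim = 2L,
                      learning_rate = 0.01, epochs = 200L, batch_size = 32L,
                      class_weights = FALSE, seed = 1L) {
  cfg <- list(feature_dims = as.integer(feature_dims),
              pool_k = as.integer(pool_k),
              gnn_out_dim = as.integer(gnn_out_dim),
              phen_out_dim = as.integer(phen_out_dim),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              class_weights = isTRUE(class_weights), seed = as.integer(seed))
  if (any(cfg$feature_dims <= 0L) || cfg$pool_k <= 0L) {
    stop("layer widths and pool_k must be positive")
  }
  class(cfg) <- "fcnet_gcnconfig"
  cfg
}

#' One spectral graph convolution layer
#'
#' H' = sigma(S H W) with S the symmetrically normalized self-looped
#' adjacency. The initial node features H are the rows of the subject's FC
#' matrix.
#'
#' @param H node features, N x d
#' @param S normalized operator from \linkS4class{BackboneGraph}
#' @param W weight matrix, d x m
#' @param activation "relu" (default) or "linear"
#' @return N x m matrix
#' @export
graphConv <- function(H, S, W, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (ncol(S) != nrow(H) || ncol(H) != nrow(W)) {
    stop(sprintf("shape mismatch: S %dx%d, H %dx%d, W %dx%d",
                 nrow(S), ncol(S), nrow(H), ncol(H), nrow(W), ncol(W)))
  }
  out <- S %*% H %*% W
  if (activation == "relu") relu(out) else out
}

#' Self-attention graph pooling (top-k)
#'
#' Scores each node with a one-filter graph convolution passed through tanh,
#' keeps the k highest-scoring nodes (ties broken toward the lower node
#' index; kept nodes returned in ascending original order so the flattened
#' representation has a stable meaning), scales the kept feature rows by
#' their scores, and restricts the adjacency to the kept nodes.
#'
#' @param H node features, N x d
#' @param A binary adjacency of the current layer
#' @param Theta pooling score filter, d x 1
#' @param k number of nodes to keep
#' @param Spool normalized operator of A + I; computed from A when omitted
#' @return list: \code{scores} (z, length N), \code{kept_index},
#'   \code{masked_scores}, \code{pooled_features} (k x d),
#'   \code{pooled_adjacency} (k x k)
#' @export
sagPool <- function(H, A, Theta, k, Spool = NULL) {
  n <- nrow(H)
  if (k > n) stop("k = ", k, " exceeds number of nodes ", n)
  if (is.null(Spool)) Spool <- normalizeAdjacency(A)
  z <- as.vector(tanh(Spool %*% H %*% Theta))
  ord <- order(-z, seq_len(n))        # stable: lower index wins ties
  idx <- sort(ord[seq_len(k)])
  zk <- z[idx]
  list(scores = z, kept_index = idx, masked_scores = zk,
       pooled_features = H[idx, , drop = FALSE] * zk,
       pooled_adjacency = A[idx, idx, drop = FALSE])
}

# Parameter initialization for the GCN (Glorot-uniform, consumes RNG).
.gcnInit <- function(n, phenLen, nClasses, cfg) {
  d1 <- cfg$feature_dims[1L]; d2 <- cfg$feature_dims[2L]
  flat <- cfg$pool_k * d2
  list(W1 = glorot(n, d1),
       W2 = glorot(d1, d2),
       Theta = glorot(d2, 1L),
       Wg = glorot(cfg$gnn_out_dim, flat), bg = numeric(cfg$gnn_out_dim),
       Wp = glorot(cfg$phen_out_dim, phenLen), bp = numeric(cfg$phen_out_dim),
       Wc = glorot(nClasses, cfg$gnn_out_dim + cfg$phen_out_dim),
       bc = numeric(nClasses))
}

# Forward pass; returns probabilities plus the cache needed for backprop.
.gcnForwardFull <- function(p, X, S, phen, k) {
  M0 <- S %*% X;  Z1 <- M0 %*% p$W1; H1 <- relu(Z1)
  M1 <- S %*% H1; Z2 <- M1 %*% p$W2; H2 <- relu(Z2)
  M2 <- S %*% H2
  zpre <- M2 %*% p$Theta
  z <- as.vector(tanh(zpre))
  n <- nrow(X)
  ord <- order(-z, seq_len(n))
  idx <- sort(ord[seq_len(k)])
  zk <- z[idx]
  Hp <- H2[idx, , drop = FALSE] * zk
  f <- as.vector(t(Hp))
  g <- as.vector(p$Wg %*% f + p$bg)
  q <- as.vector(p$Wp %*% phen + p$bp)
  u <- c(g, q)
  logits <- as.vector(p$Wc %*% u + p$bc)
  pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
  list(prob = pr, M0 = M0, Z1 = Z1, H1 = H1, M1 = M1, Z2 = Z2, H2 = H2,
       M2 = M2, z = z, idx = idx, zk = zk, Hp = Hp, f = f, u = u)
}

# Analytic gradients of the cross-entropy loss for one subject.
.gcnBackward <- function(p, cache, X, S, phen, y, weight = 1) {
  k <- length(cache$idx); d2 <- ncol(cache$H2)
  dlog <- cache$prob; dlog[y] <- dlog[y] - 1
  dlog <- dlog * weight
  g <- list()
  g$Wc <- dlog %o% cache$u
  g$bc <- dlog
  du <- as.vector(crossprod(p$Wc, dlog))
  ng <- length(p$bg)
  dg <- du[seq_len(ng)]; dq <- du[(ng + 1L):length(du)]
  g$Wp <- dq %o% phen; g$bp <- dq
  g$Wg <- dg %o% cache$f; g$bg <- dg
  df <- as.vector(crossprod(p$Wg, dg))
  dHp <- t(matrix(df, d2, k))
  Hk <- cache$H2[cache$idx, , drop = FALSE]
  dzk <- rowSums(dHp * Hk)
  dH2 <- matrix(0, nrow(cache$H2), d2)
  dH2[cache$idx, ] <- dHp * cache$zk
  dz <- numeric(length(cache$z)); dz[cache$idx] <- dzk
  dzpre <- dz * (1 - cache$z^2)
  g$Theta <- crossprod(cache$M2, dzpre)
  dH2 <- dH2 + S %*% (dzpre %o% as.vector(p$Theta))
  dZ2 <- dH2 * (cache$Z2 > 0)
  g$W2 <- crossprod(cache$M1, dZ2)
  dH1 <- S %*% dZ2 %*% t(p$W2)
  dZ1 <- dH1 * (cache$Z1 > 0)
  g$W1 <- crossprod(cache$M0, dZ1)
  g
}

#' Forward pass of a GCN model for one subject
#'
#' conv(N -> 25) -> conv(25 -> 10) -> top-k pooling (k = 10) -> flatten ->
#' linear to 15 -> concatenate with the length-2 phenotype projection ->
#' linear + softmax.
#'
#' @param model a \linkS4class{GCNModel}
#' @param fc the subject's N x N FC matrix
#' @param graph the \linkS4class{BackboneGraph}
#' @param phen phenotype encoding vector (see \code{\link{encodePhenotype}})
#' @return class probability vector (sums to 1)
#' @export
gcnForward <- function(model, fc, graph, phen) {
  if (nrow(fc) != nrow(graph@normalized)) {
    stop("FC matrix size does not match backbone graph")
  }
  .gcnForwardFull(model@params, fc, graph@normalized, phen,
                  model@config$pool_k)$prob
}

#' Train the GCN classifier
#'
#' Minimizes categorical cross-entropy with Adam (learning rate 0.01) under
#' full seed control. When a validation cohort is supplied, the parameters
#' with the best validation accuracy across epochs are returned; otherwise
#' the final parameters.
#'
#' @param cohortTrain training \linkS4class{FCCohort} (the backbone graph
#'   must have been built from these subjects only)
#' @param graph \linkS4class{BackboneGraph}
#' @param cfg a \code{\link{gcnConfig}}
#' @param validation optional validation \linkS4class{FCCohort}
#' @return a \linkS4class{GCNModel}
#' @export
trainGCN <- function(cohortTrain, graph, cfg = gcnConfig(),
                     validation = NULL) {
  y <- cohortLabels(cohortTrain)
  if (length(unique(y)) < 2L) stop("training set has a single class")
  nClasses <- length(labelNames(cohortTrain))
  S <- graph@normalized
  n <- nrow(S)
  P <- phenotypeMatrix(cohortTrain)
  mats <- fcMatrices(cohortTrain)
  ns <- nSubjects(cohortTrain)
  w <- if (cfg$class_weights) {
    tab <- tabulate(y, nClasses); (ns / (nClasses * tab))[y]
  } else rep(1, ns)

  params <- withSeed(deriveSeed(cfg$seed, "gcn-init"),
                     .gcnInit(n, nrow(P), nClasses, cfg))
  opt <- adamInit(params)
  valP <- if (!is.null(validation)) phenotypeMatrix(validation)
  valY <- if (!is.null(validation)) cohortLabels(validation)

  bestAcc <- -Inf; bestParams <- params
  hLoss <- hVal <- rep(NA_real_, cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ordEp <- withSeed(deriveSeed(cfg$seed, "gcn-shuffle", ep),
                      sample.int(ns))
    epLoss <- 0
    for (start in seq(1L, ns, by = cfg$batch_size)) {
      batch <- ordEp[start:min(start + cfg$batch_size - 1L, ns)]
      grads <- zeroLike(params)
      for (s in batch) {
        cc <- .gcnForwardFull(params, mats[, , s], S, P[, s], cfg$pool_k)
        epLoss <- epLoss - w[s] * log(max(cc$prob[y[s]], 1e-12))
        gs <- .gcnBackward(params, cc, mats[, , s], S, P[, s], y[s], w[s])
        for (nm in names(gs)) grads[[nm]] <- grads[[nm]] + gs[[nm]]
      }
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(batch)
      up <- adamStep(params, grads, opt, cfg$learning_rate)
      params <- up$params; opt <- up$state
    }
    vacc <- NA_real_
    if (!is.null(validation)) {
      pred <- vapply(seq_len(ncol(valP)), function(s) {
        which.max(.gcnForwardFull(params, fcMatrices(validation)[, , s], S,
                                  valP[, s], cfg$pool_k)$prob)
      }, integer(1))
      vacc <- mean(pred == valY)
      if (vacc > bestAcc) { bestAcc <- vacc; bestParams <- params }
    }
    hLoss[ep] <- epLoss / ns; hVal[ep] <- vacc
  }
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss = hLoss,
                     val_acc = hVal)
  if (is.null(validation)) bestParams <- params
  new("GCNModel", params = bestParams, config = unclass(cfg), history = hist)
}

#' Predict class probabilities with a trained GCN
#'
#' @param model \linkS4class{GCNModel}
#' @param cohort \linkS4class{FCCohort}
#' @param graph the \linkS4class{BackboneGraph} used at training
#' @return matrix of probabilities, subjects x classes
#' @export
predictGCN <- function(model, cohort, graph) {
  P <- phenotypeMatrix(cohort)
  mats <- fcMatrices(cohort)
  out <- t(vapply(seq_len(nSubjects(cohort)), function(s) {
    gcnForward(model, mats[, , s], graph, P[, s])
  }, numeric(length(labelNames(cohort)))))
  colnames(out) <- labelNames(cohort)
  out
}
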