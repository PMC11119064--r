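# BrainNetCNN building blocks and the (batched) discriminator network.
#
# The three connectome-specific layers operate on an N x N connectivity
# matrix: edge-to-edge (cross-shaped filters over a row and a column),
# edge-to-node (aggregation of the edges incident to each node) and
# node-to-graph (summary of all nodes into per-filter scalars). The exported
# single-filter forward functions below define the semantics; the batched
# multi-filter versions used in training are private and are tested against
# these (and against explicit loop oracles).

#' Edge-to-edge forward (single cross-shaped filter)
#'
#' out(i, j) = sum_k row_w[k] M(i, k) + sum_k col_w[k] M(k, j) + bias:
#' a weighted sum over the row and column ("cross") through each edge.
#'
#' @param M connectivity matrix, N x N
#' @param row_w,col_w length-N weights
#' @param bias scalar
#' @return N x N matrix
#' @export
e2eForward <- function(M, row_w, col_w, bias = 0) {
  n <- nrow(M)
  if (ncol(M) != n || length(row_w) != n || length(col_w) != n) {
    stop("shape mismatch in edge-to-edge filter")
  }
  r <- as.vector(M %*% row_w)          # row term, indexed by i
  cc <- as.vector(crossprod(M, col_w)) # column term, indexed by j
  outer(r, rep(1, n)) + outer(rep(1, n), cc) + bias
}

#' Edge-to-node forward (single filter)
#'
#' out(i) = sum_j w[j] M(i, j) + bias: convolution over all edges incident
#' to node i.
#'
#' @param M connectivity (or edge-map) matrix, N x N
#' @param w length-N weights
#' @param bias scalar
#' @return length-N vector
#' @export
e2nForward <- function(M, w, bias = 0) {
  if (ncol(M) != length(w)) stop("shape mismatch in edge-to-node filter")
  as.vector(M %*% w) + bias
}

#' Node-to-graph forward (single filter)
#'
#' Weighted sum of the node values plus bias: the fully connected summary of
#' all nodes into one graph-level scalar.
#'
#' @param v length-N node vector
#' @param w length-N weights
#' @param bias scalar
#' @return scalar
#' @export
n2gForward <- function(v, w, bias = 0) {
  if (length(v) != length(w)) stop("shape mismatch in node-to-graph filter")
  sum(v * w) + bias
}

## ---- batch norm over channel-major matrices (C channels x M samples) ----

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

.bnFwd <- function(x, gamma, beta, training, rm, rv) {
  if (training) {
    k <- .c_bnFwdTrain(x, gamma, beta, .BN_EPS)
    rm <- .BN_MOMENTUM * rm + (1 - .BN_MOMENTUM) * k$mu
    rv <- .BN_MOMENTUM * rv + (1 - .BN_MOMENTUM) * k$va
    list(y = k$y, xhat = k$xhat, invstd = k$invstd, rm = rm, rv = rv)
  } else {
    invstd <- 1 / sqrt(rv + .BN_EPS)
    xhat <- (x - rm) * invstd
    list(y = gamma * xhat + beta, xhat = xhat, invstd = invstd,
         rm = rm, rv = rv)
  }
}

.bnBwd <- function(dy, cache, gamma) {
  .c_bnBwd(dy, cache$xhat, cache$invstd, gamma)
}

## ---- discriminator: parameters, forward, backward ----

.discInit <- function(n, phenLen, nClasses, cfg) {
  f1 <- cfg$ece_maps; f2 <- cfg$ecn_filters; f3 <- cfg$ncg_filters
  d1 <- cfg$disc_dense
  p <- list(
    Rw = glorot(f1, n), Cw = glorot(f1, n), b1 = numeric(f1),
    bn1_g = rep(1, f1), bn1_b = numeric(f1),
    W2 = glorot(f2, n * f1), b2 = numeric(f2),
    bn2_g = rep(1, f2), bn2_b = numeric(f2),
    W3 = glorot(f3, f2 * n), b3 = numeric(f3),
    bn3_g = rep(1, f3), bn3_b = numeric(f3),
    W4 = glorot(d1, f3), b4 = numeric(d1),
    bn4_g = rep(1, d1), bn4_b = numeric(d1),
    Wp = glorot(cfg$phen_dense, phenLen), bp = numeric(cfg$phen_dense),
    Wj = glorot(cfg$joint_dense, d1 + cfg$phen_dense),
    bj = numeric(cfg$joint_dense),
    Wv = glorot(1L, cfg$joint_dense), bv = numeric(1L),
    Wcl = glorot(nClasses, cfg$joint_dense), bcl = numeric(nClasses)
  )
  stats <- list(rm1 = numeric(f1), rv1 = rep(1, f1),
                rm2 = numeric(f2), rv2 = rep(1, f2),
                rm3 = numeric(f3), rv3 = rep(1, f3),
                rm4 = numeric(d1), rv4 = rep(1, d1))
  list(params = p, stats = stats)
}

# Batched forward. M: N x N x B array, Phen: p x B. In training mode the
# batch-norm layers use batch statistics and dropout masks are drawn from
# the current RNG stream. Running moments (used in evaluation mode) are
# updated only when `updateStats` — callers keep them tracking the real-data
# distribution, not generated batches.
.discForward <- function(p, stats, M, Phen, cfg, training = FALSE,
                         updateStats = training) {
  n <- dim(M)[1L]; B <- dim(M)[3L]
  f1 <- cfg$ece_maps; f2 <- cfg$ecn_filters; f3 <- cfg$ncg_filters
  d1 <- cfg$disc_dense
  keep <- 1 - cfg$dropout
  drawU <- function(len) {
    if (training && cfg$dropout > 0) stats::runif(len) else numeric(0)
  }

  ## ECE. Row/column terms for all subjects in two matmuls:
  ## A1[(i,b), f] = sum_k M[i,k,b] Rw[f,k]; A2[(j,b), f] = sum_k M[k,j,b] Cw[f,k]
  Mi <- aperm(M, c(1, 3, 2)); dim(Mi) <- c(n * B, n)
  Mj <- aperm(M, c(2, 3, 1)); dim(Mj) <- c(n * B, n)
  A1 <- tcrossprod(Mi, p$Rw)
  A2 <- tcrossprod(Mj, p$Cw)
  ## channel-major edge maps: Ec[f, (j,i,b)] = A1[i,f,b] + A2[j,f,b] + b1[f]
  Ec <- .c_eceExpand(t(A1), t(A2), p$b1, n, B)
  bn1 <- .bnFwd(Ec, p$bn1_g, p$bn1_b, training, stats$rm1, stats$rv1)
  if (updateStats) { stats$rm1 <- bn1$rm; stats$rv1 <- bn1$rv }
  u1 <- drawU(length(bn1$y))
  Edrop <- .c_lreluDrop(bn1$y, u1, keep, 0.2)

  ## ECN: rows (j, f1), cols (i, B)
  Emat <- .c_ematPack(Edrop, n, B)
  Vpre <- p$W2 %*% Emat + p$b2                    # (f2, n*B)
  bn2 <- .bnFwd(Vpre, p$bn2_g, p$bn2_b, training, stats$rm2, stats$rv2)
  if (updateStats) { stats$rm2 <- bn2$rm; stats$rv2 <- bn2$rv }
  u2 <- drawU(length(bn2$y))
  Vpost <- .c_lreluDrop(bn2$y, u2, keep, 0.2)

  ## NCG: rows (f2, i) per subject
  Vg <- Vpost; dim(Vg) <- c(f2 * n, B)
  Gpre <- p$W3 %*% Vg + p$b3                      # (f3, B)
  bn3 <- .bnFwd(Gpre, p$bn3_g, p$bn3_b, training, stats$rm3, stats$rv3)
  if (updateStats) { stats$rm3 <- bn3$rm; stats$rv3 <- bn3$rv }
  u3 <- drawU(length(bn3$y))
  Gpost <- .c_lreluDrop(bn3$y, u3, keep, 0.2)

  ## dense(64)
  Dpre <- p$W4 %*% Gpost + p$b4
  bn4 <- .bnFwd(Dpre, p$bn4_g, p$bn4_b, training, stats$rm4, stats$rv4)
  if (updateStats) { stats$rm4 <- bn4$rm; stats$rv4 <- bn4$rv }
  u4 <- drawU(length(bn4$y))
  Dpost <- .c_lreluDrop(bn4$y, u4, keep, 0.2)

  ## phenotype branch and joint stack
  Ppre <- p$Wp %*% Phen + p$bp
  gP <- lreluGrad(Ppre)
  Pf <- Ppre * gP
  cat_ <- rbind(Dpost, Pf)
  Jpre <- p$Wj %*% cat_ + p$bj
  gJ <- lreluGrad(Jpre)
  J <- Jpre * gJ
  vlogit <- p$Wv %*% J + as.vector(p$bv)
  validity <- sigmoid(as.vector(vlogit))
  clogits <- p$Wcl %*% J + p$bcl
  probs <- softmaxCols(clogits)

  list(validity = validity, probs = probs, stats = stats,
       cache = list(M = M, Phen = Phen, Mi = Mi, Mj = Mj,
                    bn1 = bn1, u1 = u1, Emat = Emat,
                    bn2 = bn2, u2 = u2, Vg = Vg,
                    bn3 = bn3, u3 = u3, Gpost = Gpost,
                    bn4 = bn4, u4 = u4, Dpost = Dpost,
                    gP = gP, Pf = Pf, cat_ = cat_, gJ = gJ, J = J))
}

# Backward from head gradients (dvlogit 1 x B, dclogits C x B). Returns the
# parameter gradient list and, when wanted, the gradient w.r.t. the input
# matrices (needed for the generator update).
.discBackward <- function(p, cfg, fw, dvlogit, dclogits, wantInputGrad = FALSE) {
  cc <- fw$cache
  n <- dim(cc$M)[1L]; B <- dim(cc$M)[3L]
  keep <- 1 - cfg$dropout
  f1 <- cfg$ece_maps; f2 <- cfg$ecn_filters
  g <- list()
  J <- cc$J
  g$Wv <- tcrossprod(dvlogit, J); g$bv <- sum(dvlogit)
  g$Wcl <- tcrossprod(dclogits, J)
  g$bcl <- .rowSums(dclogits, nrow(dclogits), B)
  dJ <- crossprod(p$Wv, dvlogit) + crossprod(p$Wcl, dclogits)
  dJpre <- dJ * cc$gJ
  g$Wj <- tcrossprod(dJpre, cc$cat_); g$bj <- .rowSums(dJpre, nrow(dJpre), B)
  dcat <- crossprod(p$Wj, dJpre)
  d1 <- cfg$disc_dense
  dDpost <- dcat[seq_len(d1), , drop = FALSE]
  dPf <- dcat[(d1 + 1L):nrow(dcat), , drop = FALSE]
  dPpre <- dPf * cc$gP
  g$Wp <- tcrossprod(dPpre, cc$Phen); g$bp <- .rowSums(dPpre, nrow(dPpre), B)

  dDbn <- .c_lreluDropBwd(dDpost, cc$bn4$y, cc$u4, keep, 0.2)
  bb <- .bnBwd(dDbn, cc$bn4, p$bn4_g)
  g$bn4_g <- bb$dgamma; g$bn4_b <- bb$dbeta
  dDpre <- bb$dx
  g$W4 <- tcrossprod(dDpre, cc$Gpost); g$b4 <- .rowSums(dDpre, d1, B)

  dGpost <- crossprod(p$W4, dDpre)
  dGbn <- .c_lreluDropBwd(dGpost, cc$bn3$y, cc$u3, keep, 0.2)
  bb <- .bnBwd(dGbn, cc$bn3, p$bn3_g)
  g$bn3_g <- bb$dgamma; g$bn3_b <- bb$dbeta
  dGpre <- bb$dx
  g$W3 <- tcrossprod(dGpre, cc$Vg); g$b3 <- .rowSums(dGpre, nrow(dGpre), B)

  dVg <- crossprod(p$W3, dGpre)                  # (f2*n, B)
  dVpost <- dVg; dim(dVpost) <- c(f2, n * B)
  dVbn <- .c_lreluDropBwd(dVpost, cc$bn2$y, cc$u2, keep, 0.2)
  bb <- .bnBwd(dVbn, cc$bn2, p$bn2_g)
  g$bn2_g <- bb$dgamma; g$bn2_b <- bb$dbeta
  dVpre <- bb$dx
  g$W2 <- tcrossprod(dVpre, cc$Emat); g$b2 <- .rowSums(dVpre, f2, n * B)

  dEmat <- crossprod(p$W2, dVpre)                # (n*f1, n*B) rows (j,f1)
  dEc <- .c_ematUnpack(dEmat, n, B)              # (f1, n*n*B)
  dEbn <- .c_lreluDropBwd(dEc, cc$bn1$y, cc$u1, keep, 0.2)
  bb <- .bnBwd(dEbn, cc$bn1, p$bn1_g)
  g$bn1_g <- bb$dgamma; g$bn1_b <- bb$dbeta

  ## dA1[(i,b), f] = sum_j dEpre[f,(j,i,b)]; dA2[(j,b), f] = sum_i; db1 = total
  red <- .c_eceReduce(bb$dx, n, B)
  g$b1 <- red$db1
  g$Rw <- crossprod(red$dA1, cc$Mi)
  g$Cw <- crossprod(red$dA2, cc$Mj)
  dM <- NULL
  if (wantInputGrad) {
    dMi <- red$dA1 %*% p$Rw; dim(dMi) <- c(n, B, n)       # (i, b, k)
    dMj <- red$dA2 %*% p$Cw; dim(dMj) <- c(n, B, n)       # (j, b, k)
    dM <- aperm(dMi, c(1, 3, 2)) + aperm(dMj, c(3, 1, 2))
  }
  list(grads = g, dM = dM)
}

#' Discriminator forward pass (evaluation mode)
#'
#' Runs the BrainNetCNN discriminator on one subject: ECE -> batch-norm ->
#' LeakyReLU -> dropout (inactive in evaluation) -> ECN -> NCG -> dense(64),
#' concatenated with the dense(16) phenotype projection, dense(32), then the
#' sigmoid validity head and the softmax class head.
#'
#' @param model a \linkS4class{GANModel}
#' @param fc N x N connectivity matrix
#' @param phen phenotype encoding vector
#' @return list: \code{validity} in (0, 1), \code{probs} (class
#'   probabilities summing to 1)
#' @export
discriminatorForward <- function(model, fc, phen) {
  cfg <- model@config
  if (nrow(fc) != cfg$n_regions) {
    stop("FC matrix size does not match the model's n_regions")
  }
  M <- array(fc, c(nrow(fc), ncol(fc), 1L))
  fw <- .discForward(model@discriminator$params, model@discriminator$stats,
                     M, matrix(phen, ncol = 1L), cfg, training = FALSE)
  list(validity = fw$validity[1L], probs = as.vector(fw$probs[, 1L]))
}

#' Class probabilities from a trained discriminator/BrainNetCNN
#'
#' @param model \linkS4class{GANModel}
#' @param cohort \linkS4class{FCCohort}
#' @return matrix of class probabilities, subjects x classes
#' @export
predictDiscriminator <- function(model, cohort) {
  cfg <- model@config
  P <- phenotypeMatrix(cohort)
  fw <- .discForward(model@discriminator$params, model@discriminator$stats,
                     fcMatrices(cohort), P, cfg, training = FALSE)
  out <- t(fw$probs)
  colnames(out) <- labelNames(cohort)
  out
}
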