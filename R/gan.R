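#' Configuration for the conditional AC-GAN (and BrainNetCNN baseline)
#'
#' Defaults follow the published architecture: a length-50 latent vector
#' (noise plus the one-hot label and phenotype condition slots), region
#' embedding dimension d = 10, a discriminator with an ECE layer of 16
#' feature maps, an ECN layer with 64 filters and an NCG layer with 128
#' filters (each followed by batch normalization, LeakyReLU and dropout 0.5),
#' dense widths 64 (graph features), 16 (phenotype) and 32 (joint), and Adam
#' with learning rate 1e-4 and beta1 = 0.5. Epochs, batch size, LeakyReLU
#' slope and the generator's hidden width are unstated in the publication and
#' exposed here.
#'
#' @param latent_total total latent length including condition slots
#' @param embed_dim region embedding dimension d
#' @param ece_maps,ecn_filters,ncg_filters BrainNetCNN widths
#' @param disc_dense,phen_dense,joint_dense dense widths
#' @param dropout dropout rate
#' @param learning_rate,beta1 Adam settings
#' @param epochs,batch_size training loop settings
#' @param gen_hidden generator hidden width (latent -> hidden -> N*d)
#' @param class_loss_on_fake also apply the discriminator's class loss to
#'   generated samples (semi-supervised variant; off by default)
#' @param seed integer seed
#' @return list of class "fcnet_ganconfig"
#' @export
ganConfig <- function(latent_total = 50L, embed_dim = 10L, ece_maps = 16L,
                      ecn_filters = 64L, ncg_filters = 128L,
                      disc_dense = 64L, phen_dense = 16L, joint_dense = 32L,
                      dropout = 0.5, learning_rate = 1e-4, beta1 = 0.5,
                      epochs = 300L, batch_size = 16L, gen_hidden = 128L,
                      class_loss_on_fake = FALSE, seed = 1L) {
  cfg <- list(latent_total = as.integer(latent_total),
              embed_dim = as.integer(embed_dim),
              ece_maps = as.integer(ece_maps),
              ecn_filters = as.integer(ecn_filters),
              ncg_filters = as.integer(ncg_filters),
              disc_dense = as.integer(disc_dense),
              phen_dense = as.integer(phen_dense),
              joint_dense = as.integer(joint_dense),
              dropout = dropout, learning_rate = learning_rate,
              beta1 = beta1, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              gen_hidden = as.integer(gen_hidden),
              class_loss_on_fake = isTRUE(class_loss_on_fake),
              seed = as.integer(seed))
  if (any(unlist(cfg[c("latent_total", "embed_dim", "ece_maps",
                       "ecn_filters", "ncg_filters")]) <= 0L)) {
    stop("all widths must be positive")
  }
  class(cfg) <- "fcnet_ganconfig"
  cfg
}

.genInit <- function(n, cfg) {
  list(Wh = glorot(cfg$gen_hidden, cfg$latent_total),
       bh = numeric(cfg$gen_hidden),
       Wo = glorot(n * cfg$embed_dim, cfg$gen_hidden),
       bo = numeric(n * cfg$embed_dim))
}

# Batched generator forward: latent columns -> region embeddings X (N x d)
# -> A = tanh(X X^T). Returns matrices plus the cache for backprop.
.genForward <- function(gp, Z, n, d) {
  Hpre <- gp$Wh %*% Z + gp$bh
  Hg <- lrelu(Hpre)
  O <- gp$Wo %*% Hg + gp$bo
  B <- ncol(Z)
  A <- array(0, c(n, n, B))
  Xs <- vector("list", B)
  for (b in seq_len(B)) {
    X <- matrix(O[, b], n, d)
    Xs[[b]] <- X
    A[, , b] <- tanh(tcrossprod(X))
  }
  list(A = A, Xs = Xs, Hpre = Hpre, Hg = Hg, Z = Z)
}

.genBackward <- function(gp, fw, dA) {
  B <- dim(dA)[3L]
  n <- nrow(fw$Xs[[1L]]); d <- ncol(fw$Xs[[1L]])
  dO <- matrix(0, n * d, B)
  for (b in seq_len(B)) {
    dApre <- dA[, , b] * (1 - fw$A[, , b]^2)
    dX <- (dApre + t(dApre)) %*% fw$Xs[[b]]
    dO[, b] <- as.vector(dX)
  }
  g <- list()
  g$Wo <- dO %*% t(fw$Hg); g$bo <- rowSums(dO)
  dHg <- crossprod(gp$Wo, dO)
  dHpre <- dHg * lreluGrad(fw$Hpre)
  g$Wh <- dHpre %*% t(fw$Z); g$bh <- rowSums(dHpre)
  g
}

#' Generator forward pass
#'
#' The latent vector (noise plus condition slots: one-hot label and the
#' phenotype encoding) is embedded into a region-embedding matrix X (N x d,
#' one row per brain region); the output connectivity matrix is
#' A = tanh(X X^T), which is exactly symmetric with entries in (-1, 1) by
#' construction. Its diagonal is tanh(|x_i|^2) in [0, 1), not exactly 1.
#'
#' @param model a \linkS4class{GANModel} with a trained generator
#' @param noise numeric noise vector
#' @param labelOneHot one-hot class condition
#' @param phen phenotype encoding condition
#' @return generated N x N matrix
#' @export
generatorForward <- function(model, noise, labelOneHot, phen) {
  cfg <- model@config
  z <- c(noise, labelOneHot, phen)
  if (length(z) != cfg$latent_total) {
    stop("noise + condition length ", length(z),
         " != latent_total ", cfg$latent_total)
  }
  fw <- .genForward(model@generator, matrix(z, ncol = 1L),
                    cfg$n_regions, cfg$embed_dim)
  fw$A[, , 1L]
}

# Bootstrap a batch of conditioning (label, phenotype) pairs from the
# training cohort (joint resampling preserves the label-phenotype coupling).
.sampleConditions <- function(P, y, nClasses, B) {
  pick <- sample.int(length(y), B, replace = TRUE)
  Yoh <- matrix(0, nClasses, B)
  Yoh[cbind(y[pick], seq_len(B))] <- 1
  list(phen = P[, pick, drop = FALSE], y = y[pick], onehot = Yoh)
}

.latentBatch <- function(noiseLen, cond) {
  B <- ncol(cond$onehot)
  rbind(matrix(stats::runif(noiseLen * B, -1, 1), noiseLen, B),
        cond$onehot, cond$phen)
}

#' Train the conditional AC-GAN
#'
#' Alternating Adam updates (learning rate 1e-4, beta1 = 0.5). The
#' discriminator minimizes binary cross-entropy on validity (real vs
#' generated) plus categorical cross-entropy on the class labels of real
#' samples; the generator minimizes the validity loss for its samples plus
#' the class loss toward its conditioned label. Generated samples are paired
#' with their sampled conditioning phenotype. History records per-epoch
#' losses and accuracies; when a validation cohort is supplied, the
#' parameters with the best validation class accuracy are kept, with
#' validity accuracy nearest 0.5 breaking ties.
#'
#' @param cohortTrain training \linkS4class{FCCohort} (>= 2 classes)
#' @param cfg a \code{\link{ganConfig}}
#' @param validation optional validation \linkS4class{FCCohort}
#' @return a \linkS4class{GANModel} (generator + discriminator + history)
#' @export
trainGAN <- function(cohortTrain, cfg = ganConfig(), validation = NULL) {
  .trainAdversarial(cohortTrain, cfg, validation, withGenerator = TRUE)
}

#' Train the BrainNetCNN baseline classifier
#'
#' The discriminator backbone with only the class head: no generator, no
#' validity loss. Optimizer settings follow the discriminator (Adam,
#' learning rate 1e-4, beta1 = 0.5).
#'
#' @inheritParams trainGAN
#' @return a \linkS4class{GANModel} with an empty generator slot
#' @export
trainBrainNetCNN <- function(cohortTrain, cfg = ganConfig(),
                             validation = NULL) {
  .trainAdversarial(cohortTrain, cfg, validation, withGenerator = FALSE)
}

.trainAdversarial <- function(cohortTrain, cfg, validation, withGenerator) {
  y <- cohortLabels(cohortTrain)
  if (length(unique(y)) < 2L) stop("training set has a single class")
  nClasses <- length(labelNames(cohortTrain))
  P <- phenotypeMatrix(cohortTrain)
  phenLen <- nrow(P)
  mats <- fcMatrices(cohortTrain)
  n <- dim(mats)[1L]
  ns <- nSubjects(cohortTrain)
  noiseLen <- cfg$latent_total - nClasses - phenLen
  if (withGenerator && noiseLen <= 0L) {
    stop("latent_total must exceed condition length (", nClasses + phenLen, ")")
  }
  cfgFull <- c(unclass(cfg), list(n_regions = n, n_classes = nClasses,
                                  phen_len = phenLen))

  withSeed(deriveSeed(cfg$seed, "gan-train"), {
    di <- .discInit(n, phenLen, nClasses, cfg)
    dp <- di$params; dstats <- di$stats
    doOpt <- adamInit(dp)
    gp <- if (withGenerator) .genInit(n, cfg) else list()
    goOpt <- if (withGenerator) adamInit(gp)

    valP <- if (!is.null(validation)) phenotypeMatrix(validation)
    valY <- if (!is.null(validation)) cohortLabels(validation)
    best <- list(score = -Inf, tie = Inf, dp = dp, stats = dstats, gp = gp)
    hEpoch <- seq_len(cfg$epochs)
    hDloss <- hVacc <- hCacc <- hValAcc <- hValV <- rep(NA_real_, cfg$epochs)

    for (ep in seq_len(cfg$epochs)) {
      ordEp <- sample.int(ns)
      epDloss <- 0; epVacc <- 0; epCacc <- 0; nb <- 0
      for (start in seq(1L, ns, by = cfg$batch_size)) {
        idx <- ordEp[start:min(start + cfg$batch_size - 1L, ns)]
        B <- length(idx)
        Mreal <- mats[, , idx, drop = FALSE]
        Preal <- P[, idx, drop = FALSE]
        yreal <- y[idx]

        ## discriminator step: real and generated batches are forwarded
        ## separately (each normalized by its own batch statistics); running
        ## moments track the real-data distribution only
        fwR <- .discForward(dp, dstats, Mreal, Preal, cfg, training = TRUE)
        dstats <- fwR$stats
        Yoh <- matrix(0, nClasses, B)
        Yoh[cbind(yreal, seq_len(B))] <- 1
        dclogR <- (fwR$probs - Yoh) / B
        closs <- -mean(log(pmax(colSums(fwR$probs * Yoh), 1e-12)))
        if (withGenerator) {
          dvlogR <- matrix((fwR$validity - 1) / (2 * B), 1L)
          vloss <- -mean(log(pmax(fwR$validity, 1e-12))) / 2
          bwR <- .discBackward(dp, cfg, fwR, dvlogR, dclogR)

          cond <- .sampleConditions(P, y, nClasses, B)
          gfw <- .genForward(gp, .latentBatch(noiseLen, cond), n,
                             cfg$embed_dim)
          fwF <- .discForward(dp, dstats, gfw$A, cond$phen, cfg,
                              training = TRUE, updateStats = FALSE)
          dvlogF <- matrix(fwF$validity / (2 * B), 1L)
          vloss <- vloss - mean(log(pmax(1 - fwF$validity, 1e-12))) / 2
          YohF <- matrix(0, nClasses, B)
          YohF[cbind(cond$y, seq_len(B))] <- 1
          dclogF <- if (cfg$class_loss_on_fake) (fwF$probs - YohF) / B
                    else matrix(0, nClasses, B)
          if (cfg$class_loss_on_fake) {
            closs <- closs - mean(log(pmax(colSums(fwF$probs * YohF), 1e-12)))
          }
          bwF <- .discBackward(dp, cfg, fwF, dvlogF, dclogF)
          grads <- bwR$grads
          for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + bwF$grads[[nm]]
          epVacc <- epVacc + (mean(fwR$validity > 0.5) +
                              mean(fwF$validity <= 0.5)) / 2
        } else {
          vloss <- 0
          bwR <- .discBackward(dp, cfg, fwR, matrix(0, 1L, B), dclogR)
          grads <- bwR$grads
        }
        dloss <- vloss + closs
        if (!is.finite(dloss)) {
          stop("training diverged at epoch ", ep, " (non-finite loss)")
        }
        up <- adamStep(dp, grads, doOpt, cfg$learning_rate, cfg$beta1)
        dp <- up$params; doOpt <- up$state
        epDloss <- epDloss + dloss
        epCacc <- epCacc + mean(apply(fwR$probs, 2L, which.max) == yreal)
        nb <- nb + 1

        ## generator update on a fresh fake batch
        if (withGenerator) {
          cond <- .sampleConditions(P, y, nClasses, B)
          Zf <- .latentBatch(noiseLen, cond)
          gfw <- .genForward(gp, Zf, n, cfg$embed_dim)
          fwF <- .discForward(dp, dstats, gfw$A, cond$phen, cfg,
                              training = TRUE, updateStats = FALSE)
          YohF <- matrix(0, nClasses, B)
          YohF[cbind(cond$y, seq_len(B))] <- 1
          dvlogF <- matrix((fwF$validity - 1) / B, 1L)   # fool the validity head
          dclogF <- (fwF$probs - YohF) / B
          bwF <- .discBackward(dp, cfg, fwF, dvlogF, dclogF,
                               wantInputGrad = TRUE)
          gg <- .genBackward(gp, gfw, bwF$dM)
          upG <- adamStep(gp, gg, goOpt, cfg$learning_rate, cfg$beta1)
          gp <- upG$params; goOpt <- upG$state
        }
      }

      valAcc <- NA_real_; valVacc <- NA_real_
      if (!is.null(validation)) {
        fwV <- .discForward(dp, dstats, fcMatrices(validation), valP, cfg,
                            training = FALSE)
        valAcc <- mean(apply(fwV$probs, 2L, which.max) == valY)
        if (withGenerator) {
          Bv <- length(valY)
          cond <- .sampleConditions(P, y, nClasses, Bv)
          gfwV <- .genForward(gp, .latentBatch(noiseLen, cond), n,
                              cfg$embed_dim)
          fwVF <- .discForward(dp, dstats, gfwV$A, cond$phen, cfg,
                               training = FALSE)
          valVacc <- (mean(fwV$validity > 0.5) +
                      mean(fwVF$validity <= 0.5)) / 2
          tie <- abs(valVacc - 0.5)
        } else tie <- 0
        if (valAcc > best$score ||
            (valAcc == best$score && tie < best$tie)) {
          best <- list(score = valAcc, tie = tie, dp = dp, stats = dstats,
                       gp = gp)
        }
      }
      hDloss[ep] <- epDloss / nb
      hVacc[ep] <- if (withGenerator) epVacc / nb else NA_real_
      hCacc[ep] <- epCacc / nb
      hValAcc[ep] <- valAcc; hValV[ep] <- valVacc
    }
    hist <- data.frame(epoch = hEpoch, d_loss = hDloss,
                       validity_acc = hVacc, class_acc = hCacc,
                       val_acc = hValAcc, val_validity = hValV)

    if (is.null(validation)) {
      best <- list(dp = dp, stats = dstats, gp = gp)
    }
    new("GANModel",
        generator = if (withGenerator) best$gp else list(),
        discriminator = list(params = best$dp, stats = best$stats),
        config = cfgFull, history = hist)
  })
}

#' Draw synthetic FC matrices from a trained generator
#'
#' Conditions are bootstrapped jointly (label + phenotype) from a reference
#' cohort unless supplied. All outputs are exactly symmetric with entries in
#' (-1, 1); the diagonal is tanh(|x_i|^2), not 1 (see
#' \code{\link{generatorForward}}).
#'
#' @param model trained \linkS4class{GANModel}
#' @param n number of samples (0 gives an empty result)
#' @param reference \linkS4class{FCCohort} supplying the condition sampler
#' @param seed integer seed
#' @param labels optional integer class indices to condition on (recycled)
#' @return list with \code{matrices} (N x N x n array), \code{labels}
#'   (integer), \code{phen} (encoding matrix)
#' @export
generateSamples <- function(model, n, reference, seed = 1L, labels = NULL) {
  cfg <- model@config
  if (!length(model@generator)) stop("model has no generator")
  nr <- cfg$n_regions
  if (n == 0L) {
    return(list(matrices = array(0, c(nr, nr, 0L)), labels = integer(0),
                phen = matrix(0, cfg$phen_len, 0L)))
  }
  P <- phenotypeMatrix(reference)
  y <- cohortLabels(reference)
  noiseLen <- cfg$latent_total - cfg$n_classes - cfg$phen_len
  withSeed(deriveSeed(seed, "gan-sample"), {
    cond <- .sampleConditions(P, y, cfg$n_classes, n)
    if (!is.null(labels)) {
      cond$y <- rep_len(as.integer(labels), n)
      cond$onehot <- matrix(0, cfg$n_classes, n)
      cond$onehot[cbind(cond$y, seq_len(n))] <- 1
    }
    fw <- .genForward(model@generator, .latentBatch(noiseLen, cond), nr,
                      cfg$embed_dim)
    list(matrices = fw$A, labels = cond$y, phen = cond$phen)
  })
}
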