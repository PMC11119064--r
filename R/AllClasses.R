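#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.SYM_TOL <- 1e-6

#' FCCohort: a cohort of functional connectivity matrices
#'
#' Container for a set of subjects, each described by a symmetric N x N
#' Pearson correlation matrix over the same N brain regions, together with
#' the phenotype table (subject id, age, sex, optional imaging site,
#' diagnostic label).
#'
#' Matrices are stored as an N x N x S array. Invariants enforced by the
#' validity method: every slice square and symmetric within 1e-6, entries in
#' [-1, 1], unit diagonal (waived when \code{provenance} starts with
#' \code{"synthetic:GAN"}, whose generator yields diagonal tanh(|x_i|^2) < 1),
#' all subjects share region order, and labels drawn from \code{labelNames}.
#'
#' @slot matrices numeric array, N x N x S.
#' @slot phenotypes \code{DataFrame} with columns \code{subject_id},
#'   \code{age}, \code{sex} (levels F/M), optional \code{site}, \code{label}.
#' @slot regionIds character vector of N region names.
#' @slot labelNames ordered character vector of class labels.
#' @slot siteLevels character vector of site levels (lexicographic, frozen),
#'   or \code{character(0)} when the cohort has no site column.
#' @slot provenance free-text origin tag.
#' @export
setClass("FCCohort",
  representation(
    matrices   = "array",
    phenotypes = "DataFrame",
    regionIds  = "character",
    labelNames = "character",
    siteLevels = "character",
    provenance = "character"
  )
)

.validFCCohort <- function(object) {
  m <- object@matrices
  msgs <- character(0)
  if (length(dim(m)) != 3L) {
    return("matrices must be an N x N x S array")
  }
  n <- dim(m)[1L]
  if (dim(m)[2L] != n) msgs <- c(msgs, "matrix slices must be square")
  s <- dim(m)[3L]
  if (length(object@regionIds) != n) {
    msgs <- c(msgs, sprintf("regionIds length %d != N = %d",
                            length(object@regionIds), n))
  }
  ph <- object@phenotypes
  if (nrow(ph) != s) {
    msgs <- c(msgs, sprintf("phenotype rows (%d) != number of matrices (%d)",
                            nrow(ph), s))
  }
  need <- c("subject_id", "age", "sex", "label")
  miss <- setdiff(need, colnames(ph))
  if (length(miss)) {
    msgs <- c(msgs, paste("phenotypes missing column(s):",
                          paste(miss, collapse = ", ")))
  }
  if (length(msgs)) return(msgs)

  synthetic <- length(object@provenance) &&
    startsWith(object@provenance[1L], "synthetic:GAN")
  for (i in seq_len(s)) {
    x <- m[, , i]
    sid <- as.character(ph$subject_id[i])
    dev <- max(abs(x - t(x)))
    if (dev > .SYM_TOL) {
      msgs <- c(msgs, sprintf(
        "subject %s: matrix asymmetric (max |x - t(x)| = %.3g)", sid, dev))
    }
    rng <- max(abs(x))
    if (rng > 1 + 1e-12) {
      msgs <- c(msgs, sprintf(
        "subject %s: entries outside [-1, 1] (max |x| = %.6g)", sid, rng))
    }
    if (!synthetic && max(abs(diag(x) - 1)) > 1e-8) {
      msgs <- c(msgs, sprintf("subject %s: diagonal not 1", sid))
    }
  }
  if (any(!is.finite(ph$age)) || any(ph$age < 0) || any(ph$age > 120)) {
    msgs <- c(msgs, "age must be finite and within [0, 120]")
  }
  if (!all(as.character(ph$sex) %in% c("F", "M"))) {
    msgs <- c(msgs, "sex must be one of F, M")
  }
  if (!all(as.character(ph$label) %in% object@labelNames)) {
    msgs <- c(msgs, "labels outside labelNames")
  }
  if ("site" %in% colnames(ph) &&
      !all(as.character(ph$site) %in% object@siteLevels)) {
    msgs <- c(msgs, "site values outside siteLevels")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("FCCohort", .validFCCohort)

#' Construct an FCCohort
#'
#' @param matrices list of N x N matrices or an N x N x S array.
#' @param phenotypes data.frame/DataFrame with \code{subject_id}, \code{age},
#'   \code{sex}, optional \code{site}, \code{label}.
#' @param regionIds region names; default \code{R1..RN}.
#' @param labelNames class label order; default sorted unique labels.
#' @param provenance free-text origin tag.
#' @return validated \linkS4class{FCCohort}
#' @export
FCCohort <- function(matrices, phenotypes, regionIds = NULL,
                     labelNames = NULL, provenance = "unspecified") {
  if (is.list(matrices)) {
    if (!length(matrices)) stop("empty cohort: no matrices")
    n <- nrow(matrices[[1L]])
    arr <- array(NA_real_, dim = c(n, n, length(matrices)))
    for (i in seq_along(matrices)) {
      mi <- as.matrix(matrices[[i]])
      if (!all(dim(mi) == c(n, n))) {
        stop(sprintf("subject %d: matrix is %dx%d, expected %dx%d",
                     i, nrow(mi), ncol(mi), n, n))
      }
      arr[, , i] <- mi
    }
    matrices <- arr
  }
  n <- dim(matrices)[1L]
  ph <- S4Vectors::DataFrame(as.data.frame(phenotypes))
  ph$subject_id <- as.character(ph$subject_id)
  ph$sex <- as.character(ph$sex)
  ph$label <- as.character(ph$label)
  if (is.null(regionIds)) regionIds <- paste0("R", seq_len(n))
  if (is.null(labelNames)) labelNames <- sort(unique(ph$label))
  siteLevels <- if ("site" %in% colnames(ph)) {
    ph$site <- as.character(ph$site)
    sort(unique(ph$site))
  } else character(0)
  new("FCCohort", matrices = matrices, phenotypes = ph,
      regionIds = regionIds, labelNames = labelNames,
      siteLevels = siteLevels, provenance = provenance)
}

#' BackboneGraph: thresholded mean-FC adjacency with its normalization
#'
#' Binary adjacency A obtained by thresholding the mean training FC matrix at
#' cutoff tau, together with the self-looped, symmetrically normalized
#' operator S = D^(-1/2) (I + A) D^(-1/2) used by the spectral graph
#' convolution.
#'
#' @slot adjacency binary symmetric N x N matrix with zero diagonal.
#' @slot tau numeric cutoff used.
#' @slot normalized the operator S (symmetric, nonnegative, spectral
#'   radius <= 1).
#' @export
setClass("BackboneGraph",
  representation(adjacency = "matrix", tau = "numeric", normalized = "matrix")
)

setValidity("BackboneGraph", function(object) {
  a <- object@adjacency
  msgs <- character(0)
  if (nrow(a) != ncol(a)) msgs <- c(msgs, "adjacency not square")
  if (!all(a %in% c(0, 1))) msgs <- c(msgs, "adjacency not binary")
  if (any(diag(a) != 0)) msgs <- c(msgs, "adjacency diagonal must be 0")
  if (max(abs(a - t(a))) > 0) msgs <- c(msgs, "adjacency not symmetric")
  s <- object@normalized
  if (max(abs(s - t(s))) > 1e-9) msgs <- c(msgs, "normalized operator not symmetric")
  if (min(s) < 0) msgs <- c(msgs, "normalized operator has negative entries")
  if (length(msgs)) msgs else TRUE
})

#' GCNModel: parameters of the spectral GCN classifier
#'
#' @slot params named list of weight matrices/vectors (conv layers, pooling
#'   score filter, fusion projections, classifier head).
#' @slot config the \code{gcnConfig} list used at training time.
#' @slot history data.frame of per-epoch loss (and validation accuracy when a
#'   validation split was provided).
#' @export
setClass("GCNModel",
  representation(params = "list", config = "list", history = "data.frame"))

#' GANModel: generator + BrainNetCNN discriminator parameters
#'
#' @slot generator named list of generator (embedding-map) parameters;
#'   empty for the BrainNetCNN-only baseline.
#' @slot discriminator named list of discriminator parameters (ECE/ECN/NCG
#'   filters, batch-norm parameters and running statistics, dense stacks,
#'   validity and class heads).
#' @slot config the \code{ganConfig} list used at training time.
#' @slot history data.frame of per-epoch losses and accuracies.
#' @export
setClass("GANModel",
  representation(generator = "list", discriminator = "list",
                 config = "list", history = "data.frame"))

#' EvalReport: the metric panel for one evaluated model
#'
#' @slot metrics named numeric vector: accuracy, macro precision, recall
#'   (sensitivity), specificity, F1 and macro one-vs-rest AUC, all in [0, 1].
#' @slot perClass per-class metric matrix.
#' @slot foldAccuracies per-fold validation accuracies (cross-validation).
#' @slot significance list of significance results (binomial p, Wilcoxon p's).
#' @slot details list (confusion table, predictions, notes).
#' @export
setClass("EvalReport",
  representation(metrics = "numeric", perClass = "matrix",
                 foldAccuracies = "numeric", significance = "list",
                 details = "list"))

## ---- accessors ----

#' @rdname FCCohort-class
#' @param object,x an FCCohort
#' @param i subject index/logical vector
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname FCCohort-class
#' @export
setMethod("nRegions", "FCCohort", function(x) dim(x@matrices)[1L])

#' @rdname FCCohort-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname FCCohort-class
#' @export
setMethod("nSubjects", "FCCohort", function(x) dim(x@matrices)[3L])

#' @rdname FCCohort-class
#' @export
setGeneric("fcMatrices", function(x) standardGeneric("fcMatrices"))
#' @rdname FCCohort-class
#' @export
setMethod("fcMatrices", "FCCohort", function(x) x@matrices)

#' @rdname FCCohort-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname FCCohort-class
#' @export
setMethod("phenotypes", "FCCohort", function(x) x@phenotypes)

#' @rdname FCCohort-class
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))
#' @rdname FCCohort-class
#' @export
setMethod("labelNames", "FCCohort", function(x) x@labelNames)

#' @rdname FCCohort-class
#' @export
setGeneric("siteLevels", function(x) standardGeneric("siteLevels"))
#' @rdname FCCohort-class
#' @export
setMethod("siteLevels", "FCCohort", function(x) x@siteLevels)

#' Integer class labels (1-based, ordered by labelNames)
#' @param x an FCCohort
#' @export
cohortLabels <- function(x) {
  match(as.character(phenotypes(x)$label), labelNames(x))
}

#' Subset a cohort by subject index
#' @rdname FCCohort-class
#' @param j,drop,... ignored
#' @export
setMethod("[", "FCCohort", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nSubjects(x))[i]
  new("FCCohort",
      matrices = x@matrices[, , idx, drop = FALSE],
      phenotypes = x@phenotypes[idx, , drop = FALSE],
      regionIds = x@regionIds, labelNames = x@labelNames,
      siteLevels = x@siteLevels, provenance = x@provenance)
})

setMethod("show", "FCCohort", function(object) {
  cat(sprintf("FCCohort: %d subjects, %d regions\n",
              nSubjects(object), nRegions(object)))
  tab <- table(factor(as.character(object@phenotypes$label),
                      levels = object@labelNames))
  cat("  labels: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  if (length(object@siteLevels)) {
    cat("  sites:  ", paste(object@siteLevels, collapse = ", "), "\n",
        sep = "")
  }
  cat("  provenance: ", object@provenance, "\n", sep = "")
})

setMethod("show", "BackboneGraph", function(object) {
  n <- nrow(object@adjacency)
  ne <- sum(object@adjacency[upper.tri(object@adjacency)])
  cat(sprintf("BackboneGraph: %d nodes, %d edges, tau = %.4g\n",
              n, ne, object@tau))
})

setMethod("show", "GCNModel", function(object) {
  cat(sprintf("GCNModel: conv widths %s, pool k = %d, %d classes\n",
              paste(object@config$feature_dims, collapse = "/"),
              object@config$pool_k, ncol(t(object@params$Wc))))
  if (nrow(object@history)) {
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                nrow(object@history),
                object@history$loss[nrow(object@history)]))
  }
})

setMethod("show", "GANModel", function(object) {
  kind <- if (length(object@generator)) "AC-GAN" else "BrainNetCNN"
  cat(sprintf("GANModel (%s): N = %d, %d classes\n", kind,
              object@config$n_regions, object@config$n_classes))
  if (nrow(object@history)) {
    cat(sprintf("  trained %d epochs\n", nrow(object@history)))
  }
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  m <- object@metrics
  for (nm in names(m)) cat(sprintf("  %-12s %.4f\n", nm, m[[nm]]))
  if (length(object@foldAccuracies)) {
    cat("  fold accuracies: ",
        paste(sprintf("%.3f", object@foldAccuracies), collapse = " "), "\n")
  }
  if (length(object@significance)) {
    if (!is.null(object@significance$binomial_p)) {
      cat(sprintf("  binomial p = %.4g\n", object@significance$binomial_p))
    }
  }
})
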