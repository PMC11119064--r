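#' Specification of a synthetic FC cohort
#'
#' Describes a cohort of correlation matrices with known class structure:
#' a sparse positive "backbone" of population correlations shared by all
#' classes, a planted set of edges whose population correlation differs
#' between classes by \code{effect_size}, subject-level jitter on the latent
#' covariance, and simple phenotype distributions. Subjects are simulated as
#' latent Gaussian time series (T samples) whose sample Pearson correlation
#' matrix is returned — mirroring how real FC matrices arise, so that
#' thresholding behaviour downstream is realistic.
#'
#' @param n_regions number of regions N (default 20: desk-scale stand-in for
#'   the 200-region parcellations used on real data)
#' @param n_per_class subjects per class (default 40 + 40)
#' @param n_timepoints latent time-series length T (>= 30; default 150,
#'   typical of a resting-state scan)
#' @param base_density fraction of edges given a positive backbone
#'   correlation (default 0.2)
#' @param effect_edges fraction of all edges with a planted between-class
#'   difference (default 0.05)
#' @param effect_size population correlation difference on planted edges
#'   (default 0.4)
#' @param noise_sd sd of the symmetric subject-level jitter added to the
#'   latent covariance (default 0.05)
#' @param phenotype_model list: \code{age_mean} (per class), \code{age_sd},
#'   \code{sex_p} (probability of "M"), \code{site_levels} (character(0) for
#'   no site column), \code{site_probs}
#' @param seed integer seed; identical seeds give bit-identical cohorts
#' @return a validated spec list of class "fcnet_simspec"
#' @export
simSpec <- function(n_regions = 20L, n_per_class = c(40L, 40L),
                    n_timepoints = 150L, base_density = 0.2,
                    effect_edges = 0.05, effect_size = 0.4,
                    noise_sd = 0.05,
                    phenotype_model = list(), seed = 1L) {
  pm <- utils::modifyList(list(
    age_mean = 28 + 6 * seq_along(n_per_class),
    age_sd = 8,
    sex_p = 0.5,
    site_levels = character(0),
    site_probs = NULL
  ), phenotype_model)
  spec <- list(n_regions = as.integer(n_regions),
               n_per_class = as.integer(n_per_class),
               n_timepoints = as.integer(n_timepoints),
               base_density = base_density, effect_edges = effect_edges,
               effect_size = effect_size, noise_sd = noise_sd,
               phenotype_model = pm, seed = as.integer(seed))
  if (spec$n_regions < 2L) stop("n_regions must be >= 2")
  if (length(spec$n_per_class) < 1L || any(spec$n_per_class < 1L)) {
    stop("n_per_class must be positive")
  }
  if (spec$n_timepoints < 30L) {
    stop("n_timepoints must be >= 30 for stable sample correlations")
  }
  if (spec$effect_size < 0 || spec$effect_size >= 1) {
    stop("effect_size must be in [0, 1)")
  }
  class(spec) <- "fcnet_simspec"
  spec
}

# Project a symmetric matrix to the nearest correlation-like PSD matrix:
# clip eigenvalues at `eps`, reconstruct, renormalize to unit diagonal.
psdRepair <- function(m, eps = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  v <- pmax(e$values, eps)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 / tcrossprod(d)
}

.upperIdx <- function(n) which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)

#' Generate a synthetic cohort with known class structure
#'
#' Builds per-class population correlation matrices (shared backbone +
#' planted class differences, PSD-repaired by eigenvalue clipping at 1e-6
#' and re-normalization to unit diagonal), then for each subject draws T
#' multivariate-normal samples from the subject's jittered covariance and
#' returns the sample Pearson correlation matrix.
#'
#' @param spec a \code{\link{simSpec}}
#' @return list with elements \code{cohort} (\linkS4class{FCCohort}) and
#'   \code{truth} (per-class population matrices, planted edge set, spec)
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "fcnet_simspec"))
  n <- spec$n_regions
  nc <- length(spec$n_per_class)
  ut <- .upperIdx(n)
  nEdges <- nrow(ut)

  withSeed(spec$seed, {
    ## population backbone shared across classes
    nBase <- max(1L, round(spec$base_density * nEdges))
    baseEdges <- sort(sample.int(nEdges, nBase))
    baseVals <- stats::runif(nBase, 0.25, 0.45)
    B <- diag(n)
    B[ut[baseEdges, , drop = FALSE]] <- baseVals
    B <- B + t(B) - diag(diag(B))

    ## planted class effects (classes 2..nc differ from class 1)
    nEff <- max(1L, round(spec$effect_edges * nEdges))
    planted <- sort(sample.int(nEdges, nEff))
    pops <- vector("list", nc)
    pops[[1L]] <- B
    if (nc > 1L) {
      for (k in 2:nc) {
        Pk <- B
        r <- Pk[ut[planted, , drop = FALSE]]
        newR <- ifelse(r + spec$effect_size < 0.95,
                       r + spec$effect_size, r - spec$effect_size)
        if (any(abs(newR) >= 1)) {
          stop("infeasible effect_size: population correlation leaves (-1, 1)")
        }
        Pk[ut[planted, , drop = FALSE]] <- newR
        Pk[ut[planted, , drop = FALSE][, c(2, 1), drop = FALSE]] <- newR
        pops[[k]] <- Pk
      }
    }
    pops <- lapply(pops, psdRepair)

    labelNames <- if (nc == 2L) c("control", "patient")
                  else if (nc == 1L) "control"
                  else c("control", paste0("patient", seq_len(nc - 1L)))
    pm <- spec$phenotype_model
    mats <- list(); rows <- list(); sid <- 0L
    for (k in seq_len(nc)) {
      for (s in seq_len(spec$n_per_class[k])) {
        sid <- sid + 1L
        Sig <- pops[[k]]
        if (spec$noise_sd > 0) {
          J <- matrix(0, n, n)
          J[upper.tri(J)] <- stats::rnorm(nEdges, 0, spec$noise_sd)
          Sig <- psdRepair(Sig + J + t(J))
        }
        L <- chol(Sig + diag(1e-10, n))
        Z <- matrix(stats::rnorm(spec$n_timepoints * n),
                    spec$n_timepoints, n) %*% L
        m <- stats::cor(Z)
        m <- (m + t(m)) / 2
        diag(m) <- 1
        mats[[sid]] <- m
        age <- min(max(stats::rnorm(1, pm$age_mean[min(k, length(pm$age_mean))],
                                    pm$age_sd), 5), 90)
        row <- data.frame(
          subject_id = sprintf("S%03d", sid),
          age = age,
          sex = if (stats::rbinom(1, 1, pm$sex_p) == 1) "M" else "F",
          label = labelNames[k],
          stringsAsFactors = FALSE)
        if (length(pm$site_levels)) {
          row$site <- sample(pm$site_levels, 1L, prob = pm$site_probs)
        }
        rows[[sid]] <- row
      }
    }
    ph <- do.call(rbind, rows)
    if ("site" %in% colnames(ph)) {
      ph <- ph[, c("subject_id", "age", "sex", "site", "label")]
    }
    cohort <- FCCohort(mats, ph, labelNames = labelNames,
                       provenance = sprintf("synthetic:simulated seed=%d",
                                            spec$seed))
    truth <- list(population = pops,
                  planted_edges = ut[planted, , drop = FALSE],
                  label_names = labelNames, spec = spec)
    list(cohort = cohort, truth = truth)
  })
}

#' The repository's canonical worked-example cohort
#'
#' A fixed, seeded small cohort: N = 20 regions, two balanced classes of 40
#' subjects each, planted effect of 0.4 on 5\% of edges. Used throughout the
#' documentation and tests.
#'
#' @return an \linkS4class{FCCohort}
#' @export
workedExampleCohort <- function() {
  generateCohort(simSpec(n_regions = 20L, n_per_class = c(40L, 40L),
                         seed = 42L))$cohort
}
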