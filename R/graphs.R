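#' Mean functional connectivity matrix of a training set
#'
#' Element-wise arithmetic mean of the training subjects' FC matrices, with
#' the diagonal forced to zero so self-correlations never become edges.
#'
#' @param matrices an N x N x S array, a list of N x N matrices, or an
#'   \linkS4class{FCCohort}
#' @return symmetric N x N matrix with zero diagonal; attribute
#'   \code{n_subjects_averaged} records the number averaged
#' @export
meanMatrix <- function(matrices) {
  if (is(matrices, "FCCohort")) matrices <- fcMatrices(matrices)
  if (is.list(matrices)) {
    if (!length(matrices)) stop("need a non-empty set of matrices")
    matrices <- array(unlist(matrices),
                      dim = c(dim(matrices[[1L]]), length(matrices)))
  }
  if (length(dim(matrices)) != 3L || dim(matrices)[3L] == 0L) {
    stop("need a non-empty set of matrices")
  }
  m <- apply(matrices, c(1, 2), mean)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  attr(m, "n_subjects_averaged") <- dim(matrices)[3L]
  m
}

#' Edge-retention curve of a mean FC matrix
#'
#' For each candidate cutoff tau, the fraction of positive off-diagonal
#' connections retained by strict thresholding:
#' #\{upper-triangle entries > tau\} / #\{upper-triangle entries > 0\}.
#' Negative correlations are never edges and never enter the denominator.
#'
#' @param m mean matrix from \code{\link{meanMatrix}}
#' @param grid ascending numeric vector of candidate thresholds
#' @return data.frame with columns \code{tau} and \code{retained}
#'   (non-increasing in tau, 1 at tau = 0)
#' @export
retentionCurve <- function(m, grid) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("threshold grid must be strictly ascending")
  }
  up <- m[upper.tri(m)]
  pos <- up[up > 0]
  if (!length(pos)) stop("mean matrix has no positive connections")
  retained <- vapply(grid, function(tau) sum(pos > tau) / length(pos),
                     numeric(1))
  data.frame(tau = grid, retained = retained)
}

#' Elbow of a retention curve
#'
#' Operationalizes the visual elbow criterion as the grid point of maximum
#' perpendicular distance to the chord joining the curve's endpoints
#' (Kneedle-style). Both axes are first mapped to [0, 1] so the choice is
#' unit-independent. Ties break toward the smaller tau; a flat or perfectly
#' linear curve (max distance < 1e-9) returns the smallest grid tau with a
#' warning.
#'
#' @param curve data.frame from \code{\link{retentionCurve}}
#' @return the selected tau
#' @export
selectElbow <- function(curve) {
  if (nrow(curve) < 3L) stop("need at least 3 grid points")
  x <- curve$tau; y <- curve$retained
  xs <- (x - x[1L]) / max(x[length(x)] - x[1L], .Machine$double.eps)
  ry <- range(y)
  ys <- if (diff(ry) > 0) (y - ry[1L]) / diff(ry) else y * 0
  ## distance from (xs, ys) to the chord through first and last points
  x0 <- xs[1L]; y0 <- ys[1L]; x1 <- xs[length(xs)]; y1 <- ys[length(ys)]
  d <- abs((y1 - y0) * xs - (x1 - x0) * ys + x1 * y0 - y1 * x0) /
    sqrt((y1 - y0)^2 + (x1 - x0)^2)
  if (max(d) < 1e-9) {
    warning("retention curve has no elbow (linear/flat); returning smallest tau")
    return(x[1L])
  }
  x[which.max(d)]
}

#' Binarize a mean matrix into a backbone graph
#'
#' A[i, j] = 1 iff the mean matrix exceeds tau strictly (ties at tau are
#' dropped) and i != j. Also computes the self-looped, symmetrically
#' normalized propagation operator S = D^(-1/2) (I + A) D^(-1/2) used by the
#' spectral graph convolution; self-loops guarantee every degree >= 1, so
#' isolated nodes are harmless. An empty edge set is allowed with a warning.
#'
#' @param m mean matrix (zero diagonal)
#' @param tau nonnegative cutoff
#' @return a \linkS4class{BackboneGraph}
#' @export
binarize <- function(m, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  a <- (m > tau) * 1
  diag(a) <- 0
  a <- a * (t(a) == a)  # defensive; m symmetric implies a symmetric
  if (sum(a) == 0) warning("tau = ", tau, " leaves an empty edge set")
  new("BackboneGraph", adjacency = a, tau = as.numeric(tau),
      normalized = normalizeAdjacency(a))
}

#' Symmetric normalization of a self-looped adjacency
#'
#' S = D^(-1/2) (I + A) D^(-1/2) with D the degree matrix of I + A.
#'
#' @param a binary adjacency (zero diagonal)
#' @return the normalized operator S
#' @export
normalizeAdjacency <- function(a) {
  at <- a + diag(nrow(a))
  dinv <- 1 / sqrt(rowSums(at))
  at * tcrossprod(dinv)
}

#' Build the backbone graph for a training cohort
#'
#' Convenience wrapper: mean training FC, retention curve over a grid,
#' elbow selection (unless \code{tau} overrides it, as when reproducing a
#' published cutoff), binarization.
#'
#' @param training an \linkS4class{FCCohort} (training subjects only) or
#'   matrix array/list
#' @param grid threshold grid (default \code{seq(0, 0.5, by = 0.01)})
#' @param tau optional user-supplied cutoff overriding the elbow rule
#' @return a \linkS4class{BackboneGraph}; the retention curve is attached as
#'   attribute \code{"curve"}
#' @export
buildBackbone <- function(training, grid = seq(0, 0.5, by = 0.01),
                          tau = NULL) {
  m <- meanMatrix(training)
  grid <- grid[grid < max(m)]
  curve <- retentionCurve(m, grid)
  if (is.null(tau)) tau <- selectElbow(curve)
  g <- binarize(m, tau)
  attr(g, "curve") <- curve
  g
}
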