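# Internal helpers: seed scoping and deterministic seed derivation.

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage-specific seed from a global seed
#'
#' Counter-based fan-out: each named stage gets its own stream so adding a
#' stage never perturbs the randomness of earlier stages. Result is always in
#' [1, 2^31 - 2].
#'
#' @param seed integer global seed
#' @param label character stage label (e.g. "split", "init", "sampling")
#' @param counter optional integer counter (e.g. fold or repetition index)
#' @return integer seed
#' @export
deriveSeed <- function(seed, label, counter = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  v <- (as.double(seed) * 48271 + h * 8191 + as.double(counter) * 131071)
  as.integer(v %% (2^31 - 2)) + 1L
}

relu <- function(x) pmax(x, 0)
lrelu <- function(x, slope = 0.2) x * (slope + (1 - slope) * (x > 0))
lreluGrad <- function(x, slope = 0.2) slope + (1 - slope) * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Column-wise softmax of a matrix of logits (classes x batch).
softmaxCols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# Glorot/Xavier-uniform initialization, consuming the current RNG stream.
glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Adam optimizer over a named list of arrays.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    u <- .c_adamUpdate(params[[nm]], grads[[nm]], state$m[[nm]],
                       state$v[[nm]], lr, beta1, beta2, eps, c1, c2)
    params[[nm]] <- u$p
    state$m[[nm]] <- u$m
    state$v[[nm]] <- u$v
  }
  list(params = params, state = state)
}

# Zero-filled gradient accumulator shaped like `params`.
zeroLike <- function(params) lapply(params, function(p) p * 0)
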