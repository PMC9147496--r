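# Internal neural-network plumbing shared by the MIP classifier and the
# 3D outcome net: activations, parameter init, Adam, interpolation helpers.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.elu <- function(x) ifelse(x > 0, x, expm1(x))
.eluGrad <- function(x) ifelse(x > 0, 1, exp(x))

# He-scaled Gaussian init; fanIn is the number of inputs feeding one unit.
.heInit <- function(dims, fanIn) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dim = dims)
}

# Adam state and update over a flat named list of parameter arrays.
.adamInit <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamUpdate <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Corner-aligned linear interpolation matrix mapping nIn samples to nOut.
.interpMatrix <- function(nIn, nOut) {
  A <- matrix(0, nOut, nIn)
  if (nIn == 1L) {
    A[, 1L] <- 1
    return(A)
  }
  u <- (seq_len(nOut) - 1) * (nIn - 1) / (nOut - 1)
  lo <- pmin(floor(u), nIn - 2)
  fr <- u - lo
  for (i in seq_len(nOut)) {
    A[i, lo[i] + 1L] <- 1 - fr[i]
    A[i, lo[i] + 2L] <- fr[i]
  }
  A
}

# Euclidean pixel distances from every (row, col) pixel to point (row, col).
.distMatrix <- function(nr, nc, point) {
  dr <- (seq_len(nr) - point[1])^2
  dc <- (seq_len(nc) - point[2])^2
  sqrt(outer(dr, dc, `+`))
}

# Run fn with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
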