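# Flat named parameter collections ("model weights") and the Adam
# optimiser used for all local training. A weight set is a plain named
# list of base matrices, which makes federated averaging exact elementwise
# arithmetic.

#' Elementwise arithmetic on named weight collections
#'
#' Model weights are named lists of numeric matrices with identical
#' name/shape signatures across clients, so server-side aggregation is
#' plain arithmetic. These helpers implement that arithmetic and check
#' signatures.
#'
#' @param a,b Named lists of numeric matrices with identical signatures.
#' @param s Scalar multiplier.
#' @return A named list of matrices.
#' @export
weights_add <- function(a, b) {
  check_signature(a, b)
  purrr::map2(a, b, `+`)
}

#' @rdname weights_add
#' @export
weights_scale <- function(a, s) {
  lapply(a, function(m) m * s)
}

#' @rdname weights_add
#' @export
weights_zero_like <- function(a) {
  lapply(a, function(m) m * 0)
}

check_signature <- function(a, b) {
  if (!identical(names(a), names(b))) {
    stop("weight collections have different parameter names", call. = FALSE)
  }
  ok <- purrr::map2_lgl(a, b, function(x, y) all(dim(x) == dim(y)))
  if (!all(ok)) {
    stop("weight shape mismatch for parameter(s): ",
         paste(names(a)[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Glorot-uniform initialisation, the GAT convention.
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

adam_init <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = weights_zero_like(params),
    v = weights_zero_like(params)
  )
}

# One Adam update. `grads` is a named list aligned with `params`.
adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}

# Bind a named list of plain matrices onto the tape as parameter nodes,
# returning a parallel list of nodes; `collect_grads` reads them back.
params_to_nodes <- function(params) {
  lapply(params, ag_param)
}

collect_grads <- function(nodes) {
  lapply(nodes, ag_grad)
}
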