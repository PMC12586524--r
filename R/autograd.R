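# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a "node": an environment holding `value`
# (a base matrix), the accumulated `grad`, the parent nodes, and a backward
# closure that pushes the node's gradient into its parents. Nodes are
# appended to a tape in creation order, so a single reverse sweep over the
# tape implements backpropagation. The engine is deliberately small: only
# the operations the attention networks in this package need.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()

ag_reset <- function() {
  .ag$tape <- list()
  invisible(NULL)
}

ag_new_node <- function(value, parents = list(), backfn = NULL) {
  stopifnot(is.matrix(value))
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  .ag$tape[[length(.ag$tape) + 1L]] <- n
  n$idx <- length(.ag$tape)
  class(n) <- "ag_node"
  n
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Leaf nodes. Constants take part in the graph but receive no gradient use;
# parameters are the leaves whose grads the optimiser reads.
ag_const <- function(value) ag_new_node(as_mat(value))
ag_param <- function(value) ag_new_node(as_mat(value))

ag_value <- function(n) n$value
ag_grad <- function(n) {
  if (is.null(n$grad)) matrix(0, nrow(n$value), ncol(n$value)) else n$grad
}

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @noRd
ag_backward <- function(root) {
  stopifnot(length(root$value) == 1L)
  tape <- .ag$tape
  for (i in seq_len(root$idx)) tape[[i]]$grad <- NULL
  root$grad <- matrix(1, 1, 1)
  for (i in seq(root$idx, 1L)) {
    n <- tape[[i]]
    if (!is.null(n$grad) && !is.null(n$backfn)) n$backfn(n)
  }
  invisible(NULL)
}

ag_matmul <- function(a, b) {
  ag_new_node(a$value %*% b$value, list(a, b), function(n) {
    ag_accum(n$parents[[1]], n$grad %*% t(n$parents[[2]]$value))
    ag_accum(n$parents[[2]], t(n$parents[[1]]$value) %*% n$grad)
  })
}

ag_add <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ag_new_node(a$value + b$value, list(a, b), function(n) {
    ag_accum(n$parents[[1]], n$grad)
    ag_accum(n$parents[[2]], n$grad)
  })
}

ag_sub <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ag_new_node(a$value - b$value, list(a, b), function(n) {
    ag_accum(n$parents[[1]], n$grad)
    ag_accum(n$parents[[2]], -n$grad)
  })
}

# b is a 1 x d row vector broadcast over the rows of a (bias add).
ag_add_bias <- function(a, b) {
  stopifnot(nrow(b$value) == 1L, ncol(a$value) == ncol(b$value))
  ag_new_node(sweep(a$value, 2L, b$value[1L, ], "+"), list(a, b), function(n) {
    ag_accum(n$parents[[1]], n$grad)
    ag_accum(n$parents[[2]], matrix(colSums(n$grad), nrow = 1L))
  })
}

ag_mul <- function(a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ag_new_node(a$value * b$value, list(a, b), function(n) {
    ag_accum(n$parents[[1]], n$grad * n$parents[[2]]$value)
    ag_accum(n$parents[[2]], n$grad * n$parents[[1]]$value)
  })
}

ag_scale <- function(a, s) {
  ag_new_node(a$value * s, list(a), function(n) {
    ag_accum(n$parents[[1]], n$grad * s)
  })
}

ag_relu <- function(a) {
  ag_new_node(pmax(a$value, 0), list(a), function(n) {
    ag_accum(n$parents[[1]], n$grad * (n$parents[[1]]$value > 0))
  })
}

ag_leakyrelu <- function(a, slope = 0.2) {
  v <- a$value
  ag_new_node(ifelse(v > 0, v, slope * v), list(a), function(n) {
    x <- n$parents[[1]]$value
    ag_accum(n$parents[[1]], n$grad * ifelse(x > 0, 1, slope))
  })
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_new_node(s, list(a), function(n) {
    s <- n$value
    ag_accum(n$parents[[1]], n$grad * s * (1 - s))
  })
}

# Row-wise softmax restricted to the support of `mask` (0/1 matrix).
# Entries off the support are exactly 0 in the output. Every row of the
# mask must have at least one nonzero entry (callers add self-edges).
ag_masked_softmax <- function(a, mask) {
  stopifnot(is.matrix(mask), all(dim(mask) == dim(a$value)),
            all(rowSums(mask) > 0))
  x <- a$value
  x[mask == 0] <- -Inf
  mx <- apply(x, 1L, max)
  e <- exp(x - mx)
  e[mask == 0] <- 0
  p <- e / rowSums(e)
  ag_new_node(p, list(a), function(n) {
    p <- n$value
    g <- n$grad
    dot <- rowSums(g * p)
    ag_accum(n$parents[[1]], p * (g - dot))
  })
}

# E[i, j] = u[i] + v[j] for column vectors u, v (n x 1): the additive
# pairwise score grid used by attention layers.
ag_outer_sum <- function(u, v) {
  stopifnot(ncol(u$value) == 1L, ncol(v$value) == 1L)
  nu <- nrow(u$value); nv <- nrow(v$value)
  val <- matrix(u$value[, 1L], nu, nv) +
    matrix(v$value[, 1L], nu, nv, byrow = TRUE)
  ag_new_node(val, list(u, v), function(n) {
    ag_accum(n$parents[[1]], matrix(rowSums(n$grad), ncol = 1L))
    ag_accum(n$parents[[2]], matrix(colSums(n$grad), ncol = 1L))
  })
}

ag_gather_rows <- function(a, idx) {
  ag_new_node(a$value[idx, , drop = FALSE], list(a), function(n) {
    g <- matrix(0, nrow(n$parents[[1]]$value), ncol(n$parents[[1]]$value))
    for (r in seq_along(idx)) {
      g[idx[r], ] <- g[idx[r], ] + n$grad[r, ]
    }
    ag_accum(n$parents[[1]], g)
  })
}

ag_cbind <- function(...) {
  nodes <- list(...)
  vals <- lapply(nodes, ag_value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_new_node(do.call(cbind, vals), nodes, function(n) {
    for (k in seq_along(n$parents)) {
      ag_accum(n$parents[[k]], n$grad[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

# Column-major reshape (R's native fill order), gradient reshaped back.
ag_reshape <- function(a, nr, nc) {
  stopifnot(length(a$value) == nr * nc)
  ag_new_node(matrix(as.vector(a$value), nr, nc), list(a), function(n) {
    p <- n$parents[[1]]
    ag_accum(p, matrix(as.vector(n$grad), nrow(p$value), ncol(p$value)))
  })
}

ag_mean_rows <- function(a) {
  n_rows <- nrow(a$value)
  ag_new_node(matrix(colMeans(a$value), nrow = 1L), list(a), function(n) {
    g <- matrix(rep(n$grad[1L, ] / n_rows, each = n_rows), nrow = n_rows)
    ag_accum(n$parents[[1]], g)
  })
}

ag_sum <- function(a) {
  ag_new_node(matrix(sum(a$value), 1, 1), list(a), function(n) {
    g <- n$grad[1L, 1L]
    ag_accum(n$parents[[1]], matrix(g, nrow(n$parents[[1]]$value),
                                    ncol(n$parents[[1]]$value)))
  })
}

# Numerically stable sum of elementwise binary cross-entropy with logits:
# sum over entries of softplus(z) - y * z, gradient sigmoid(z) - y.
ag_bce_logits <- function(logits, y) {
  stopifnot(all(dim(y) == dim(logits$value)))
  z <- logits$value
  loss <- sum(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  ag_new_node(matrix(loss, 1, 1), list(logits), function(n) {
    z <- n$parents[[1]]$value
    ag_accum(n$parents[[1]], n$grad[1L, 1L] * (1 / (1 + exp(-z)) - y))
  })
}

# Sum of squared differences against a constant target matrix.
ag_sq_err <- function(a, target) {
  stopifnot(all(dim(target) == dim(a$value)))
  d <- a$value - target
  ag_new_node(matrix(sum(d * d), 1, 1), list(a), function(n) {
    ag_accum(n$parents[[1]],
             n$grad[1L, 1L] * 2 * (n$parents[[1]]$value - target))
  })
}
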