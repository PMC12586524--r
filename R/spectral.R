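# Structure-sensitive spectral features: unnormalised graph Laplacian,
# truncated symmetric eigendecomposition with deterministic sign
# canonicalisation, fixed-size flattening, client-level averaging, and the
# Gaussian mechanism for differential privacy.

#' Unnormalised graph Laplacian
#'
#' `L = D - A` with `D = diag(rowSums(A))`. Rows sum to zero.
#'
#' @param A Symmetric adjacency matrix with zero diagonal.
#' @return The Laplacian matrix.
#' @export
laplacian <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-12)) {
    stop("adjacency must be symmetric")
  }
  diag(rowSums(A)) - A
}

#' Truncated eigendecomposition of a symmetric matrix
#'
#' Returns the `M` largest eigenvalues in descending order and their
#' unit-norm eigenvectors, sign-canonicalised so each vector's
#' largest-magnitude entry is positive (first such index on ties). Within
#' a numerically degenerate eigenvalue cluster, columns are ordered by the
#' canonicalised vectors' lexicographic order so the output is
#' deterministic regardless of solver arbitrariness. If `M > n` all `n`
#' pairs are returned (padding happens downstream).
#'
#' @param L Symmetric matrix.
#' @param M Number of eigenpairs to retain.
#' @return List with `values` (descending) and `vectors` (n x m, columns
#'   aligned with `values`).
#' @export
truncated_eigendecomposition <- function(L, M) {
  L <- as.matrix(L)
  if (!isSymmetric(unname(L), tol = 1e-10)) stop("matrix must be symmetric")
  n <- nrow(L)
  m <- min(as.integer(M), n)
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  vals <- e$values[seq_len(m)]
  vecs <- e$vectors[, seq_len(m), drop = FALSE]
  for (k in seq_len(m)) vecs[, k] <- canonical_sign(vecs[, k])
  # deterministic order inside degenerate clusters
  k <- 1L
  while (k <= m) {
    j <- k
    while (j < m && abs(vals[j + 1L] - vals[k]) < 1e-9) j <- j + 1L
    if (j > k) {
      block <- vecs[, k:j, drop = FALSE]
      ord <- do.call(order, as.data.frame(t(block)))
      vecs[, k:j] <- block[, ord, drop = FALSE]
    }
    k <- j + 1L
  }
  list(values = vals, vectors = vecs)
}

canonical_sign <- function(u) {
  i <- which.max(abs(u))
  if (u[i] < 0) -u else u
}

#' Flatten truncated eigenvectors into a fixed-size spectral feature
#'
#' Columns are zero-padded to `M` eigenpairs and the node dimension is
#' zero-padded (or truncated) to `N_max`, then flattened row-major, so
#' every graph in a federation maps to a vector of the same length
#' `N_max * M`.
#'
#' @param U n x m eigenvector matrix (m <= M).
#' @param M Retained-eigenpair budget.
#' @param N_max Node budget.
#' @return Numeric vector of length `N_max * M`.
#' @export
spectral_feature <- function(U, M, N_max) {
  U <- as.matrix(U)
  if (ncol(U) > M) stop("U has more columns than the eigenpair budget M")
  full <- matrix(0, N_max, M)
  nr <- min(nrow(U), N_max)
  full[seq_len(nr), seq_len(ncol(U))] <- U[seq_len(nr), , drop = FALSE]
  as.vector(t(full)) # row-major flatten
}

#' Spectral feature of one graph
#'
#' Laplacian, truncated eigendecomposition, fixed-size flatten.
#'
#' @param g A `fedgat_graph` (or a bare adjacency matrix).
#' @param M,N_max See [spectral_feature()].
#' @return Numeric vector of length `N_max * M`.
#' @export
graph_spectral_feature <- function(g, M = 8, N_max = 32) {
  A <- if (inherits(g, "fedgat_graph")) g$adjacency else as.matrix(g)
  ed <- truncated_eigendecomposition(laplacian(A), M)
  spectral_feature(ed$vectors, M, N_max)
}

#' Client-level spectral summary
#'
#' Arithmetic mean of the per-graph spectral features.
#'
#' @param features Nonempty list of equal-length numeric vectors.
#' @return The mean vector.
#' @export
client_spectral_summary <- function(features) {
  if (length(features) == 0L) stop("no spectral features to summarise")
  lens <- vapply(features, length, integer(1))
  if (length(unique(lens)) != 1L) stop("spectral feature length mismatch")
  Reduce(`+`, features) / length(features)
}

#' Privatise a client summary with the Gaussian mechanism
#'
#' Adds iid Gaussian noise with scale `sigma = delta_f / epsilon` to every
#' coordinate. With `delta_f = "auto"` the replace-one L2 sensitivity of a
#' mean of `n_graphs` flattened column-unit-norm eigenvector matrices is
#' used: each feature has L2 norm at most `sqrt(M)`, so replacing one
#' graph moves the mean by at most `2 sqrt(M) / n_graphs`.
#'
#' @param summary Numeric vector (the client mean spectral feature).
#' @param epsilon Positive privacy budget (default 10).
#' @param delta_f Sensitivity, or `"auto"`.
#' @param n_graphs Number of graphs behind the mean (needed for "auto").
#' @param M Eigenpair budget (needed for "auto").
#' @param seed Optional integer seed for the noise draw.
#' @return A `fedgat_private_summary`: `g_tilde`, `epsilon`, `sigma`,
#'   `delta_f`.
#' @export
privatize <- function(summary, epsilon = 10, delta_f = "auto",
                      n_graphs = NULL, M = NULL, seed = NULL) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (identical(delta_f, "auto")) {
    if (is.null(n_graphs) || is.null(M)) {
      stop("delta_f = 'auto' needs n_graphs and M")
    }
    delta_f <- 2 * sqrt(M) / n_graphs
  }
  sigma <- delta_f / epsilon
  noise <- if (is.null(seed)) {
    stats::rnorm(length(summary), 0, sigma)
  } else {
    with_seed(seed, stats::rnorm(length(summary), 0, sigma))
  }
  structure(list(g_tilde = summary + noise, epsilon = epsilon,
                 sigma = sigma, delta_f = delta_f),
            class = "fedgat_private_summary")
}

#' Privatised spectral summary of a client shard
#'
#' @param shard A `fedgat_shard` (or plain list of graphs).
#' @param config A [fedgat_config()] (uses its `spectral` block).
#' @param seed Optional seed for the noise draw.
#' @return A `fedgat_private_summary`.
#' @export
shard_spectral_summary <- function(shard, config = fedgat_config(),
                                   seed = NULL) {
  graphs <- if (inherits(shard, "fedgat_shard")) shard$graphs else shard
  cfg <- config$spectral
  feats <- lapply(graphs, graph_spectral_feature, M = cfg$M,
                  N_max = cfg$N_max)
  privatize(client_spectral_summary(feats), epsilon = cfg$epsilon,
            delta_f = cfg$delta_f, n_graphs = length(graphs), M = cfg$M,
            seed = seed)
}
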