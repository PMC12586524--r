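# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

triangle_adj <- function() {
  A <- matrix(1, 3, 3); diag(A) <- 0; A
}

star_adj <- function(leaves = 3) {
  n <- leaves + 1L
  A <- matrix(0, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1
  A
}

random_sym_adj <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p]
  A[on] <- 1
  A + t(A)
}

# Small multi-label graph with random features
make_graph <- function(id, A, C = 2, d = 3, labels = NULL) {
  n <- nrow(A)
  mlgraph(id, A, matrix(stats::rnorm(n * d), n, d),
          labels %||% stats::rbinom(C, 1, 0.5))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny deterministic federated dataset (no structure, for plumbing tests)
make_tiny_dataset <- function(K = 2, n_graphs = 4, C = 2, seed = 1) {
  withr::with_seed(seed, {
    space <- label_space(paste0("lab", seq_len(C)))
    shards <- lapply(seq_len(K), function(k) {
      graphs <- lapply(seq_len(n_graphs), function(i) {
        make_graph(sprintf("k%d_g%d", k, i), random_sym_adj(5), C = C)
      })
      client_shard(paste0("client", k), graphs, space)
    })
    federated_dataset(shards, space)
  })
}

# Fast small config for training-path tests
tiny_config <- function(...) {
  fedgat_config(deep_merge_test(list(
    labels = list(embedding_dim = 12),
    ae = list(epochs = 15L, hidden_dim = 6L, heads = 2L),
    spectral = list(M = 3L, N_max = 8L),
    backbone = list(hidden = c(8L, 8L), heads = c(2L, 2L, 1L),
                    head_hidden = 8L),
    train = list(local_epochs = 1L, batch_size = 8L),
    federation = list(rounds = 2L, test_frac = 0.25, eval_every = 1L)
  ), list(...)))
}

deep_merge_test <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- deep_merge_test(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
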