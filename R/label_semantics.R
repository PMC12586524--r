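# Client-specific label semantics: label frequency counting, smoothed
# ratio normalisation into distribution weights, label embeddings from a
# pluggable provider, and the weighted label semantic graph with nested
# multi-scale adjacencies.

#' Count per-label absolute frequencies in a shard
#'
#' `f[k]` is the number of graphs in the shard that carry label `k`.
#'
#' @param shard A `fedgat_shard`.
#' @return Integer vector of length C, named by label.
#' @export
count_label_frequencies <- function(shard) {
  stopifnot(inherits(shard, "fedgat_shard"))
  Y <- do.call(rbind, lapply(shard$graphs, function(g) g$labels))
  f <- as.integer(colSums(Y))
  names(f) <- shard$label_space$names
  f
}

#' Normalise label frequencies into distribution weights
#'
#' The default is the smoothed ratio
#' \eqn{w_k = (f_k + \epsilon) / \sum_j (f_j + \epsilon)} (additive
#' smoothing, so rare labels keep positive weight). An exponential
#' (softmax) variant over `f / max(f + eps)` is available behind
#' `method = "exp"` but is off by default.
#'
#' @param f Nonnegative frequency vector.
#' @param eps Smoothing constant, must be positive. Default 1 (Laplace
#'   smoothing).
#' @param method `"ratio"` (default) or `"exp"`.
#' @return Weight vector summing to 1.
#' @export
compute_label_weights <- function(f, eps = 1, method = c("ratio", "exp")) {
  method <- match.arg(method)
  if (eps <= 0) stop("smoothing eps must be positive")
  if (any(f < 0)) stop("frequencies must be nonnegative")
  if (method == "ratio") {
    w <- (f + eps) / sum(f + eps)
  } else {
    z <- (f + eps) / max(f + eps)
    w <- exp(z) / sum(exp(z))
  }
  names(w) <- names(f)
  w
}

#' Embed label names as vectors
#'
#' The default provider is a deterministic stub: each label name is
#' hashed to a seed that draws a pseudo-random vector, then L2-normalised.
#' It preserves the contract the downstream modules need (deterministic,
#' unit-norm, distinct names give distinct vectors) without an external
#' text encoder. Any callable mapping a name to a numeric vector can be
#' supplied instead (e.g. a real text-encoder hook); its outputs are
#' L2-normalised to the same contract.
#'
#' @param space A [label_space()].
#' @param provider `"stub"` or a function `name -> numeric vector`.
#' @param dim Embedding dimension for the stub provider.
#' @return A list with `vectors` (C x d matrix, rows unit-norm) and `dim`.
#' @export
embed_labels <- function(space, provider = "stub", dim = 64) {
  stopifnot(inherits(space, "fedgat_label_space"))
  fetch <- if (is.function(provider)) {
    provider
  } else if (identical(provider, "stub")) {
    function(name) stub_embedding(name, dim)
  } else {
    stop("unknown embedding provider: ", provider)
  }
  rows <- lapply(space$names, function(nm) {
    v <- tryCatch(as.numeric(fetch(nm)), error = function(e) {
      stop("embedding provider failed for label '", nm, "': ",
           conditionMessage(e), call. = FALSE)
    })
    if (!all(is.finite(v))) {
      stop("embedding provider returned non-finite values for '", nm, "'")
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  })
  d <- length(rows[[1]])
  if (any(vapply(rows, length, integer(1)) != d)) {
    stop("embedding provider returned inconsistent dimensions")
  }
  L <- do.call(rbind, rows)
  rownames(L) <- space$names
  list(vectors = L, dim = d)
}

stub_embedding <- function(name, dim) {
  with_seed(stable_hash(paste0("label-embedding:", name)),
            stats::rnorm(dim))
}

#' Scale label embeddings by distribution weights
#'
#' @param emb Output of [embed_labels()].
#' @param w Weight vector of length C.
#' @return C x d matrix of weighted embeddings.
#' @export
weight_embeddings <- function(emb, w) {
  L <- emb$vectors
  if (length(w) != nrow(L)) stop("weight vector length != number of labels")
  L * as.numeric(w)
}

#' Build the weighted label semantic graph
#'
#' Nodes are the weighted label embeddings; dense edge weights are cosine
#' similarities (0 against a zero vector). The scale-1 adjacency keeps
#' off-diagonal pairs whose similarity reaches a threshold (default: the
#' mean off-diagonal similarity of this graph); scale-s adjacency is the
#' support of the s-th boolean power of scale 1 (s-hop reachability),
#' self-edges excluded, so edge sets are nested across scales.
#'
#' @param L_tilde C x d matrix of weighted embeddings.
#' @param scales Integer scales, default `1:3`.
#' @param threshold Either `"mean"` or an absolute cosine threshold.
#' @return A `fedgat_label_graph` with `node_embeddings`, `edge_weights`
#'   and `scale_adjacencies`.
#' @export
build_label_graph <- function(L_tilde, scales = 1:3, threshold = "mean") {
  L_tilde <- as.matrix(L_tilde)
  C <- nrow(L_tilde)
  S <- cosine_matrix(L_tilde)
  if (C == 1L) {
    adj1 <- matrix(0, 1, 1)
  } else {
    off <- S[upper.tri(S) | lower.tri(S)]
    tau <- if (identical(threshold, "mean")) mean(off) else as.numeric(threshold)
    adj1 <- (S >= tau) * 1
    diag(adj1) <- 0
  }
  scales <- sort(unique(as.integer(scales)))
  adjs <- list()
  reach <- adj1
  cur <- 1L
  for (s in scales) {
    while (cur < s) {
      # one more hop: boolean matrix power support, cumulative
      reach <- ((reach %*% adj1 + reach) > 0) * 1
      diag(reach) <- 0
      cur <- cur + 1L
    }
    adjs[[as.character(s)]] <- reach
  }
  structure(list(node_embeddings = L_tilde, edge_weights = S,
                 scale_adjacencies = adjs),
            class = "fedgat_label_graph")
}

# Cosine similarity matrix with the zero-vector convention: any pair
# involving a zero row has similarity 0 (including its own diagonal).
cosine_matrix <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  Y <- X
  nz <- nrm > 0
  Y[nz, ] <- X[nz, , drop = FALSE] / nrm[nz]
  Y[!nz, ] <- 0
  S <- Y %*% t(Y)
  S <- (S + t(S)) / 2
  S[S > 1] <- 1
  S[S < -1] <- -1
  S
}

#' Run the label-semantics pipeline for one shard
#'
#' Convenience wrapper: frequencies, weights, embeddings, weighted
#' embeddings and the label semantic graph in one call.
#'
#' @param shard A `fedgat_shard`.
#' @param config A [fedgat_config()] (uses its `labels` block).
#' @return List with `frequencies`, `weights`, `embeddings`,
#'   `weighted_embeddings` and `label_graph`.
#' @export
label_semantics <- function(shard, config = fedgat_config()) {
  cfg <- config$labels
  f <- count_label_frequencies(shard)
  if (isTRUE(config$ablate$weighted)) {
    w <- rep(1 / length(f), length(f))
    names(w) <- names(f)
  } else {
    w <- compute_label_weights(f, eps = cfg$smoothing_eps,
                               method = cfg$weight_method)
  }
  emb <- embed_labels(shard$label_space, provider = cfg$embedding_provider,
                      dim = cfg$embedding_dim)
  Lt <- weight_embeddings(emb, w)
  scales <- if (isTRUE(config$ablate$multiscale)) 1L else cfg$scales
  lg <- build_label_graph(Lt, scales = scales,
                          threshold = cfg$similarity_threshold)
  list(frequencies = f, weights = w, embeddings = emb,
       weighted_embeddings = Lt, label_graph = lg)
}
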