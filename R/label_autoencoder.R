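# Multi-scale graph attention autoencoder over the weighted label
# semantic graph. The encoder computes, per scale, averaged multi-head
# attention features whose coefficients come from a learned pairwise
# similarity scorer applied to graph-propagated linear projections of the
# node embeddings; per-scale features are concatenated into the label
# context embedding F. Training masks edges at random each epoch and
# reconstructs the unmasked embeddings through a mirrored single-scale
# attention decoder.

# ---- plain-numeric operations (the testable module surface) --------------

#' Neural pairwise similarity score
#'
#' `MLP(concat(z_i, z_j))` where `z = A_hat %*% (L_tilde %*% W)` is the
#' masked-graph-propagated linear projection of the node embeddings and
#' the MLP has one LeakyReLU hidden layer. Asymmetric in (i, j) by
#' construction (concatenation order).
#'
#' @param scorer List with `W1a`, `W1b`, `b1`, `w2`, `b2`.
#' @param z_i,z_j Projected, propagated embeddings (numeric vectors).
#' @param slope LeakyReLU slope.
#' @return Scalar score.
#' @export
neural_similarity <- function(scorer, z_i, z_j, slope = 0.2) {
  h <- as.numeric(z_i %*% scorer$W1a + z_j %*% scorer$W1b) + scorer$b1[1L, ]
  h <- ifelse(h > 0, h, slope * h)
  sum(h * scorer$w2[, 1L]) + scorer$b2[1L, 1L]
}

#' Softmax attention coefficients over a neighborhood
#'
#' @param scores Numeric vector of similarity scores over the (nonempty)
#'   neighborhood of a node.
#' @return Coefficients summing to 1.
#' @export
attention_coefficients <- function(scores) {
  if (length(scores) == 0L) stop("empty neighborhood: no scores")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Single-head attention feature for one node
#'
#' `f_i = ReLU(sum_j alpha_ij V l_tilde_j)` over the neighbors of `i` in
#' `adj` (self-edge fallback applied beforehand by callers).
#'
#' @param alpha Coefficients over the neighbors (in index order of `nbrs`).
#' @param V d x d_h value map.
#' @param L_tilde C x d node embeddings.
#' @param nbrs Integer indices of the neighbors.
#' @return Length-d_h feature vector.
#' @export
attend <- function(alpha, V, L_tilde, nbrs) {
  pre <- as.numeric(alpha %*% (L_tilde[nbrs, , drop = FALSE] %*% V))
  pmax(pre, 0)
}

#' Averaged multi-head attention feature for one node
#'
#' `ReLU((1/K) sum_k sum_j alpha^k_ij V^k l_tilde_j)`: the ReLU is applied
#' to the average of the per-head pre-activations, so K = 1 reduces
#' exactly to the single-head rule.
#'
#' @param head_alphas List of per-head coefficient vectors.
#' @param head_Vs List of per-head value maps.
#' @param L_tilde C x d node embeddings.
#' @param nbrs Neighbor indices.
#' @return Length-d_h feature vector.
#' @export
multi_head_feature <- function(head_alphas, head_Vs, L_tilde, nbrs) {
  K <- length(head_alphas)
  stopifnot(K >= 1L, length(head_Vs) == K)
  Lj <- L_tilde[nbrs, , drop = FALSE]
  pre <- Reduce(`+`, lapply(seq_len(K), function(k) {
    as.numeric(head_alphas[[k]] %*% (Lj %*% head_Vs[[k]]))
  })) / K
  pmax(pre, 0)
}

#' Masked reconstruction loss
#'
#' Mean over nodes of the squared reconstruction error summed over
#' embedding dimensions.
#'
#' @param X,Recon Matrices of identical shape (targets, reconstructions).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(X, Recon) {
  X <- as.matrix(X); Recon <- as.matrix(Recon)
  stopifnot(all(dim(X) == dim(Recon)))
  mean(rowSums((X - Recon)^2))
}

# ---- parameters ----------------------------------------------------------

ae_param_names <- function(scales, heads) {
  nms <- "W"
  for (s in scales) for (k in seq_len(heads)) {
    p <- sprintf("s%d_h%d_", s, k)
    nms <- c(nms, paste0(p, c("W1a", "W1b", "b1", "w2", "b2", "V")))
  }
  c(nms, paste0("dec_", c("W", "W1a", "W1b", "b1", "w2", "b2", "V",
                          "out", "out_b")))
}

#' Initialise label-autoencoder parameters
#'
#' One shared input projection `W` (d -> d_h), per-scale per-head pairwise
#' scorers and value maps, and a single-scale attention decoder followed
#' by a linear map back to d. Glorot-uniform initialisation.
#'
#' @param d Input embedding dimension.
#' @param d_h Hidden width.
#' @param heads Heads per scale.
#' @param scales Integer scales.
#' @param seed Integer seed.
#' @return Named list of matrices (a weight collection).
#' @export
ae_init_params <- function(d, d_h, heads, scales, seed = 1L) {
  dF <- length(scales) * d_h
  with_seed(seed, {
    p <- list(W = glorot(d, d_h))
    for (s in scales) for (k in seq_len(heads)) {
      pre <- sprintf("s%d_h%d_", s, k)
      p[[paste0(pre, "W1a")]] <- glorot(d_h, d_h)
      p[[paste0(pre, "W1b")]] <- glorot(d_h, d_h)
      p[[paste0(pre, "b1")]] <- matrix(0, 1, d_h)
      p[[paste0(pre, "w2")]] <- glorot(d_h, 1L)
      p[[paste0(pre, "b2")]] <- matrix(0, 1, 1)
      p[[paste0(pre, "V")]] <- glorot(d, d_h)
    }
    p$dec_W <- glorot(dF, d_h)
    p$dec_W1a <- glorot(d_h, d_h)
    p$dec_W1b <- glorot(d_h, d_h)
    p$dec_b1 <- matrix(0, 1, d_h)
    p$dec_w2 <- glorot(d_h, 1L)
    p$dec_b2 <- matrix(0, 1, 1)
    p$dec_V <- glorot(dF, d_h)
    p$dec_out <- glorot(d_h, d)
    p$dec_out_b <- matrix(0, 1, d)
    p
  })
}

# Rows with no neighbors get a self-edge so softmax is defined.
support_with_fallback <- function(adj) {
  supp <- (adj != 0) * 1
  empty <- rowSums(supp) == 0
  if (any(empty)) diag(supp)[empty] <- 1
  supp
}

# Row-normalised propagation operator over the (masked) scale-1 graph,
# with self-loops so every row is defined.
propagation_operator <- function(adj) {
  P <- (adj != 0) * 1
  diag(P) <- 1
  P / rowSums(P)
}

# One attention block on the tape: scores from the pairwise scorer over
# all ordered pairs, masked softmax on `supp`, attended values.
ae_attention_block <- function(nodes, prefix, x_in, Ahat, supp, slope) {
  C <- nrow(x_in$value)
  Z <- ag_matmul(ag_const(Ahat), ag_matmul(x_in, nodes[[paste0(prefix, "W")]]))
  pair_i <- rep(seq_len(C), times = C) # i varies fastest: column-major fill
  pair_j <- rep(seq_len(C), each = C)
  ZI <- ag_gather_rows(Z, pair_i)
  ZJ <- ag_gather_rows(Z, pair_j)
  H <- ag_leakyrelu(
    ag_add_bias(ag_add(ag_matmul(ZI, nodes[[paste0(prefix, "W1a")]]),
                       ag_matmul(ZJ, nodes[[paste0(prefix, "W1b")]])),
                nodes[[paste0(prefix, "b1")]]),
    slope)
  sc <- ag_add_bias(ag_matmul(H, nodes[[paste0(prefix, "w2")]]),
                    nodes[[paste0(prefix, "b2")]])
  S <- ag_reshape(sc, C, C) # S[i, j] = score(i, j)
  A <- ag_masked_softmax(S, supp)
  ag_matmul(A, ag_matmul(x_in, nodes[[paste0(prefix, "V")]]))
}

# Encoder forward on the tape. `adjs` is the named list of scale
# adjacencies (possibly of the masked graph); `Ahat` the propagation
# operator. Returns the C x (n_scales * d_h) embedding node.
ae_encode_node <- function(nodes, Lt_node, adjs, Ahat, heads, slope = 0.2) {
  per_scale <- lapply(names(adjs), function(s) {
    supp <- support_with_fallback(adjs[[s]])
    pres <- lapply(seq_len(heads), function(k) {
      # shared projection W, per-head scorer + value map
      block_nodes <- nodes
      block_nodes[[sprintf("s%s_h%d_W", s, k)]] <- nodes$W
      ae_attention_block(block_nodes, sprintf("s%s_h%d_", s, k),
                         Lt_node, Ahat, supp, slope)
    })
    ag_relu(ag_scale(Reduce(ag_add, pres), 1 / heads))
  })
  if (length(per_scale) == 1L) per_scale[[1]] else do.call(ag_cbind, per_scale)
}

ae_decode_node <- function(nodes, F_node, adj1, Ahat, slope = 0.2) {
  supp <- support_with_fallback(adj1)
  H <- ag_relu(ae_attention_block(nodes, "dec_", F_node, Ahat, supp, slope))
  ag_add_bias(ag_matmul(H, nodes$dec_out), nodes$dec_out_b)
}

#' Encode a label graph into the label context embedding F
#'
#' Deterministic forward pass (no masking) of the multi-scale attention
#' encoder: per-scale averaged multi-head attention features concatenated
#' per label.
#'
#' @param params Autoencoder weights from [ae_init_params()] or
#'   [train_autoencoder()].
#' @param label_graph A `fedgat_label_graph`.
#' @param heads Number of heads per scale (must match `params`).
#' @return C x (n_scales * d_h) matrix `F`.
#' @export
ae_encode <- function(params, label_graph, heads = 4) {
  adjs <- label_graph$scale_adjacencies
  adj1 <- adjs[[1]]
  ag_reset()
  nodes <- params_to_nodes(params)
  Lt <- ag_const(label_graph$node_embeddings)
  Fn <- ae_encode_node(nodes, Lt, adjs, propagation_operator(adj1), heads)
  out <- ag_value(Fn)
  ag_reset()
  out
}

#' Train the label autoencoder
#'
#' Each epoch drops scale-1 edges independently with probability
#' `mask_rate`, rebuilds the coarser scales from the masked graph,
#' encodes, decodes, and takes one Adam step on the reconstruction loss
#' against the unmasked embeddings.
#'
#' @param label_graph A `fedgat_label_graph`.
#' @param config A [fedgat_config()] (uses its `ae` block).
#' @param seed Integer seed (initialisation and masking).
#' @return List of class `fedgat_autoencoder`: `params`, `loss_trace`,
#'   `F` (the final deterministic encoding), `heads`.
#' @export
train_autoencoder <- function(label_graph, config = fedgat_config(),
                              seed = 1L) {
  cfg <- config$ae
  Lt <- label_graph$node_embeddings
  d <- ncol(Lt)
  scales <- as.integer(names(label_graph$scale_adjacencies))
  params <- ae_init_params(d, cfg$hidden_dim, cfg$heads, scales,
                           seed = derive_seed(seed, "ae-init"))
  opt <- adam_init(params, lr = cfg$lr)
  adj1 <- label_graph$scale_adjacencies[[1]]
  loss_trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    masked <- with_seed(derive_seed(seed, "ae-mask", ep),
                        mask_edges(adj1, cfg$mask_rate))
    adjs_m <- rebuild_scales(masked, scales)
    Ahat <- propagation_operator(masked)
    ag_reset()
    nodes <- params_to_nodes(params)
    Lt_node <- ag_const(Lt)
    Fn <- ae_encode_node(nodes, Lt_node, adjs_m, Ahat, cfg$heads)
    Recon <- ae_decode_node(nodes, Fn, masked, Ahat)
    loss <- ag_scale(ag_sq_err(Recon, Lt), 1 / nrow(Lt))
    loss_val <- ag_value(loss)[1L, 1L]
    if (!is.finite(loss_val)) {
      stop("autoencoder loss became non-finite at epoch ", ep,
           " (last finite loss: ",
           if (ep > 1L) signif(loss_trace[ep - 1L], 6) else "none", ")")
    }
    loss_trace[ep] <- loss_val
    ag_backward(loss)
    st <- adam_step(opt, params, collect_grads(nodes))
    opt <- st$state
    params <- st$params
  }
  ag_reset()
  structure(list(params = params,
                 loss_trace = loss_trace,
                 F = ae_encode(params, label_graph, heads = cfg$heads),
                 heads = cfg$heads),
            class = "fedgat_autoencoder")
}

mask_edges <- function(adj1, mask_rate) {
  if (mask_rate <= 0) return(adj1)
  C <- nrow(adj1)
  keep <- matrix(TRUE, C, C)
  up <- which(upper.tri(adj1) & adj1 != 0)
  drop <- up[stats::runif(length(up)) < mask_rate]
  keep[drop] <- FALSE
  keep <- keep & t(keep)
  adj1 * keep
}

rebuild_scales <- function(adj1, scales) {
  adjs <- list()
  reach <- adj1
  cur <- 1L
  for (s in sort(scales)) {
    while (cur < s) {
      reach <- ((reach %*% adj1 + reach) > 0) * 1
      diag(reach) <- 0
      cur <- cur + 1L
    }
    adjs[[as.character(s)]] <- reach
  }
  adjs
}
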