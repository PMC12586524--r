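# Backbone multi-label classifier: a three-layer multi-head graph
# attention network over each input graph, mean-pooling readout, and a
# classifier MLP whose input concatenates the pooled graph vector with
# the flattened label context embedding F and the graph's spectral
# feature. Multi-label output through independent sigmoids.

# ---- plain-numeric operations (the testable module surface) --------------

#' Unnormalised GAT attention score
#'
#' `LeakyReLU(a . [W h_i || W h_j])`; callers normalise scores over each
#' node's neighborhood with a softmax.
#'
#' @param h_i,h_j Node feature vectors.
#' @param W Layer weight matrix (d_in x d_out).
#' @param a Attention vector of length 2 * d_out.
#' @param slope LeakyReLU slope.
#' @return Scalar score.
#' @export
gat_attention <- function(h_i, h_j, W, a, slope = 0.2) {
  z <- sum(a * c(as.numeric(h_i %*% W), as.numeric(h_j %*% W)))
  if (z > 0) z else slope * z
}

#' One multi-head GAT layer (plain numeric forward)
#'
#' Attention scores per Eq.-style additive attention, softmax-normalised
#' over each node's neighborhood (isolated nodes get a self-edge), heads
#' averaged before the activation.
#'
#' @param H n x d_in node feature matrix.
#' @param adj Adjacency matrix (support defines neighborhoods; self-edges
#'   added for isolated nodes).
#' @param layer List with `W` (d_in x d_out) and `heads`: a list of
#'   attention vectors, each split as `a_src`, `a_dst` (d_out x 1 each).
#' @param slope LeakyReLU slope.
#' @param activation `"relu"` or `"identity"` applied to the averaged
#'   head outputs.
#' @param return_attention Also return the per-head softmax-normalised
#'   attention matrices.
#' @return n x d_out matrix, or (with `return_attention`) a list with
#'   `H` and `attention`.
#' @export
gat_layer <- function(H, adj, layer, slope = 0.2, activation = "relu",
                      return_attention = FALSE) {
  supp <- support_with_fallback(adj)
  HW <- H %*% layer$W
  pre <- 0
  atts <- vector("list", length(layer$heads))
  for (k in seq_along(layer$heads)) {
    head <- layer$heads[[k]]
    s1 <- as.numeric(HW %*% head$a_src)
    s2 <- as.numeric(HW %*% head$a_dst)
    E <- outer(s1, rep(1, length(s2))) + outer(rep(1, length(s1)), s2)
    E <- ifelse(E > 0, E, slope * E)
    E[supp == 0] <- -Inf
    E <- E - apply(E, 1L, max)
    A <- exp(E) * (supp != 0)
    A <- A / rowSums(A)
    atts[[k]] <- A
    pre <- pre + A %*% HW
  }
  pre <- pre / length(layer$heads)
  out <- if (identical(activation, "relu")) pmax(pre, 0) else pre
  if (return_attention) list(H = out, attention = atts) else out
}

#' Mean-pooling graph readout
#'
#' @param H Node embedding matrix.
#' @return Row vector (1 x d): the column means.
#' @export
readout <- function(H) {
  matrix(colMeans(as.matrix(H)), nrow = 1L)
}

#' Fuse pooled graph, label context and spectral features and classify
#'
#' `logits = MLP(concat(x_pool, flatten(F), g))` with one hidden ReLU
#' layer; probabilities are elementwise sigmoids (no cross-label
#' normalisation). Setting `use_labels`/`use_spectral` to `FALSE` zeroes
#' the corresponding block (ablations), keeping dimensions fixed.
#'
#' @param x_pool 1 x d pooled graph vector.
#' @param F_flat Flattened label context embedding (numeric vector).
#' @param g Spectral feature vector.
#' @param head List with `W1`, `b1`, `W2`, `b2`.
#' @param use_labels,use_spectral Ablation switches.
#' @return List with `logits` and `probabilities` (length-C vectors).
#' @export
fuse_and_classify <- function(x_pool, F_flat, g, head,
                              use_labels = TRUE, use_spectral = TRUE) {
  if (!use_labels) F_flat <- F_flat * 0
  if (!use_spectral) g <- g * 0
  inp <- matrix(c(as.numeric(x_pool), as.numeric(F_flat), as.numeric(g)),
                nrow = 1L)
  if (ncol(inp) != nrow(head$W1)) {
    stop("classifier head input dimension mismatch: got ", ncol(inp),
         ", head expects ", nrow(head$W1))
  }
  h <- pmax(inp %*% head$W1 + head$b1, 0)
  logits <- as.numeric(h %*% head$W2 + head$b2)
  list(logits = logits, probabilities = 1 / (1 + exp(-logits)))
}

#' Joint training loss
#'
#' Mean over the batch of `ae_loss + BCE(y, p)`, with the binary
#' cross-entropy summed over the C labels of each graph (the multi-label
#' reading of a sigmoid-output cross-entropy).
#'
#' @param probabilities n x C matrix of predicted probabilities.
#' @param labels n x C binary matrix.
#' @param ae_loss Scalar autoencoder reconstruction loss term.
#' @return Scalar loss.
#' @export
total_loss <- function(probabilities, labels, ae_loss = 0) {
  p <- pmin(pmax(as.matrix(probabilities), 1e-12), 1 - 1e-12)
  y <- as.matrix(labels)
  stopifnot(all(dim(p) == dim(y)))
  bce <- -rowSums(y * log(p) + (1 - y) * log(1 - p))
  val <- mean(ae_loss + bce)
  if (!is.finite(val)) stop("non-finite classification loss")
  val
}

# ---- parameters ----------------------------------------------------------

#' Initialise backbone + classifier-head parameters
#'
#' Layer widths `hidden[1] -> hidden[2] -> C`; `extra_in` is the length
#' of the concatenated auxiliary block (flattened F plus spectral g)
#' appended to the pooled C-vector at the classifier head.
#'
#' @param d_x Input node-feature dimension.
#' @param C Number of labels.
#' @param extra_in Length of flatten(F) plus length of g.
#' @param config A [fedgat_config()] (uses its `backbone` block).
#' @param seed Integer seed.
#' @return Named list of matrices (a weight collection).
#' @export
backbone_init_params <- function(d_x, C, extra_in,
                                 config = fedgat_config(), seed = 1L) {
  cfg <- config$backbone
  dims_in <- c(d_x, cfg$hidden[1], cfg$hidden[2])
  dims_out <- c(cfg$hidden[1], cfg$hidden[2], C)
  with_seed(seed, {
    p <- list()
    for (l in 1:3) {
      p[[sprintf("gat%d_W", l)]] <- glorot(dims_in[l], dims_out[l])
      for (k in seq_len(cfg$heads[l])) {
        p[[sprintf("gat%d_h%d_a_src", l, k)]] <- glorot(dims_out[l], 1L)
        p[[sprintf("gat%d_h%d_a_dst", l, k)]] <- glorot(dims_out[l], 1L)
      }
    }
    head_in <- C + extra_in
    p$head_W1 <- glorot(head_in, cfg$head_hidden)
    p$head_b1 <- matrix(0, 1, cfg$head_hidden)
    p$head_W2 <- glorot(cfg$head_hidden, C)
    p$head_b2 <- matrix(0, 1, C)
    p
  })
}

# ---- tape forward --------------------------------------------------------

gat_layer_node <- function(nodes, l, H, supp, heads, slope, relu = TRUE) {
  HW <- ag_matmul(H, nodes[[sprintf("gat%d_W", l)]])
  pres <- lapply(seq_len(heads), function(k) {
    s1 <- ag_matmul(HW, nodes[[sprintf("gat%d_h%d_a_src", l, k)]])
    s2 <- ag_matmul(HW, nodes[[sprintf("gat%d_h%d_a_dst", l, k)]])
    E <- ag_leakyrelu(ag_outer_sum(s1, s2), slope)
    A <- ag_masked_softmax(E, supp)
    ag_matmul(A, HW)
  })
  out <- ag_scale(Reduce(ag_add, pres), 1 / heads)
  if (relu) ag_relu(out) else out
}

# Forward pass for one graph on the tape: returns the 1 x C logits node.
backbone_forward_node <- function(nodes, graph, F_flat, g_spec, config) {
  cfg <- config$backbone
  supp <- support_with_fallback(graph$adjacency)
  H <- ag_const(graph$node_features)
  H <- gat_layer_node(nodes, 1L, H, supp, cfg$heads[1], cfg$leaky_slope)
  H <- gat_layer_node(nodes, 2L, H, supp, cfg$heads[2], cfg$leaky_slope)
  H <- gat_layer_node(nodes, 3L, H, supp, cfg$heads[3], cfg$leaky_slope,
                      relu = FALSE)
  x_pool <- ag_mean_rows(H)
  if (isTRUE(config$ablate$graph)) F_flat <- F_flat * 0
  inp <- ag_cbind(x_pool, ag_const(matrix(F_flat, nrow = 1L)),
                  ag_const(matrix(g_spec, nrow = 1L)))
  h <- ag_relu(ag_add_bias(ag_matmul(inp, nodes$head_W1), nodes$head_b1))
  ag_add_bias(ag_matmul(h, nodes$head_W2), nodes$head_b2)
}

#' Predict label probabilities for a list of graphs
#'
#' @param params Backbone weights ([backbone_init_params()] shape).
#' @param graphs List of `fedgat_graph` objects.
#' @param F_flat Flattened label context embedding of the owning client.
#' @param g_list List of spectral features aligned with `graphs`.
#' @param config A [fedgat_config()].
#' @return n x C matrix of probabilities.
#' @export
backbone_predict <- function(params, graphs, F_flat, g_list,
                             config = fedgat_config()) {
  out <- matrix(NA_real_, length(graphs),
                ncol(params$head_W2))
  for (i in seq_along(graphs)) {
    ag_reset()
    nodes <- params_to_nodes(params)
    logits <- backbone_forward_node(nodes, graphs[[i]], F_flat,
                                    g_list[[i]], config)
    out[i, ] <- 1 / (1 + exp(-ag_value(logits)[1L, ]))
  }
  ag_reset()
  out
}

#' Train the backbone classifier on one client's graphs
#'
#' Minimises the joint loss (constant autoencoder term plus per-graph
#' multi-label binary cross-entropy) with Adam, shuffled mini-batches.
#'
#' @param params Starting weights.
#' @param graphs Training graphs.
#' @param F_flat Flattened label context embedding.
#' @param g_list Spectral features aligned with `graphs`.
#' @param ae_loss Constant reconstruction-loss term added to every batch.
#' @param config A [fedgat_config()].
#' @param epochs Number of epochs (defaults to `train$local_epochs`).
#' @param seed Integer seed (shuffling).
#' @return List with `params` and `epoch_losses`.
#' @export
backbone_train <- function(params, graphs, F_flat, g_list, ae_loss = 0,
                           config = fedgat_config(), epochs = NULL,
                           seed = 1L) {
  tr <- config$train
  epochs <- epochs %||% tr$local_epochs
  opt <- adam_init(params, lr = tr$lr)
  n <- length(graphs)
  epoch_losses <- numeric(epochs)
  if (epochs == 0L) return(list(params = params, epoch_losses = numeric(0)))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "shuffle", ep), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / tr$batch_size))
    ep_loss <- 0
    for (b in batches) {
      ag_reset()
      nodes <- params_to_nodes(params)
      terms <- lapply(b, function(i) {
        logits <- backbone_forward_node(nodes, graphs[[i]], F_flat,
                                        g_list[[i]], config)
        ag_bce_logits(logits, matrix(graphs[[i]]$labels, nrow = 1L))
      })
      loss <- ag_scale(Reduce(ag_add, terms), 1 / length(b))
      loss_val <- ag_value(loss)[1L, 1L] + ae_loss
      if (!is.finite(loss_val)) {
        stop("backbone loss became non-finite at epoch ", ep)
      }
      ep_loss <- ep_loss + loss_val * length(b)
      ag_backward(loss)
      st <- adam_step(opt, params, collect_grads(nodes))
      opt <- st$state
      params <- st$params
    }
    epoch_losses[ep] <- ep_loss / n
  }
  ag_reset()
  list(params = params, epoch_losses = epoch_losses)
}
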