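# Backbone classifier: attention scores, layer equivariance, readout,
# fusion head, loss, and the finite-difference gradient check of the
# full fused forward pass.

make_layer <- function(d_in, d_out, heads = 1) {
  list(W = matrix(rnorm(d_in * d_out), d_in, d_out),
       heads = lapply(seq_len(heads), function(k) {
         list(a_src = matrix(rnorm(d_out), d_out, 1),
              a_dst = matrix(rnorm(d_out), d_out, 1))
       }))
}

test_that("GAT attention scores follow the additive LeakyReLU rule", {
  withr::with_seed(2, {
    d <- 3; W <- matrix(rnorm(d * 2), d, 2)
    h_i <- rnorm(d); h_j <- rnorm(d)
    expect_equal(gat_attention(h_i, h_j, W, rep(0, 4)), 0)
    # positive pre-activation: identity
    a <- rep(1, 4); hp <- abs(h_i); Wp <- abs(W)
    z <- sum(a * c(hp %*% Wp, abs(h_j) %*% Wp))
    expect_equal(gat_attention(hp, abs(h_j), Wp, a), z)
    # known negative pre-activation scaled by the slope
    W1 <- matrix(c(1, 0, 0, 0), 2, 2)
    got <- gat_attention(c(-1, 0), c(0, 0), W1, c(1, 0, 0, 0), slope = 0.2)
    expect_equal(got, -0.2)
  })
})

test_that("GAT layers are node-permutation equivariant", {
  withr::with_seed(19, {
    for (i in 1:10) {
      n <- sample(4:9, 1)
      A <- random_sym_adj(n, 0.5)
      H <- matrix(rnorm(n * 4), n, 4)
      layer <- make_layer(4, 6, heads = 2)
      out <- gat_layer(H, A, layer)
      perm <- sample(n)
      out_p <- gat_layer(H[perm, , drop = FALSE], A[perm, perm], layer)
      expect_equal(out_p, out[perm, , drop = FALSE], tolerance = 1e-10)
    }
    # identical features + zero attention vector: uniform attention,
    # identical output rows
    n <- 5
    A <- random_sym_adj(n, 0.6)
    H <- matrix(1, n, 3)
    layer <- make_layer(3, 4, heads = 1)
    layer$heads[[1]]$a_src[] <- 0; layer$heads[[1]]$a_dst[] <- 0
    out <- gat_layer(H, A, layer)
    expect_equal(out, matrix(out[1, ], n, 4, byrow = TRUE))
    # isolated node attends only to itself
    A0 <- matrix(0, 3, 3); A0[1, 2] <- A0[2, 1] <- 1
    H3 <- matrix(rnorm(9), 3, 3)
    l3 <- make_layer(3, 2, heads = 1)
    out3 <- gat_layer(H3, A0, l3)
    expect_equal(out3[3, ], pmax(H3[3, , drop = FALSE] %*% l3$W, 0)[1, ])
  })
})

test_that("mean readout is size-invariant and linear", {
  withr::with_seed(5, {
    H <- matrix(rnorm(8), 2, 4)
    expect_equal(readout(H[1, , drop = FALSE]), H[1, , drop = FALSE])
    expect_equal(readout(rbind(H[1, ], H[1, ])), H[1, , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(readout(3 * H), 3 * readout(H))
  })
})

test_that("fusion head concatenates blocks and supports ablations", {
  withr::with_seed(8, {
    C <- 3
    x_pool <- matrix(rnorm(C), 1)
    F_flat <- rnorm(6); g <- rnorm(4)
    head <- list(W1 = matrix(rnorm(13 * 5), 13, 5), b1 = matrix(0, 1, 5),
                 W2 = matrix(rnorm(5 * C), 5, C), b2 = matrix(0, 1, C))
    # zero head: probability one half everywhere
    zero_head <- list(W1 = head$W1 * 0, b1 = head$b1, W2 = head$W2 * 0,
                      b2 = head$b2)
    p <- fuse_and_classify(x_pool, F_flat, g, zero_head)
    expect_equal(p$probabilities, rep(0.5, C))
    expect_length(p$logits, C)
    # ablating the label context equals feeding zeros for F
    p_abl <- fuse_and_classify(x_pool, F_flat, g, head, use_labels = FALSE)
    p_zero <- fuse_and_classify(x_pool, F_flat * 0, g, head)
    expect_identical(p_abl, p_zero)
    p_abl2 <- fuse_and_classify(x_pool, F_flat, g, head, use_spectral = FALSE)
    expect_identical(p_abl2, fuse_and_classify(x_pool, F_flat, g * 0, head))
    expect_error(fuse_and_classify(x_pool, c(F_flat, 1), g, head),
                 "dimension mismatch")
  })
})

test_that("the joint loss is mean ae + summed per-label cross-entropy", {
  y <- rbind(c(1, 0, 1), c(0, 0, 1))
  expect_equal(total_loss(y, y), 0, tolerance = 1e-9)
  p_half <- matrix(0.5, 2, 3)
  expect_equal(total_loss(p_half, y), 3 * log(2))
  expect_equal(total_loss(p_half, y, ae_loss = 1.5), 3 * log(2) + 1.5)
  withr::with_seed(4, {
    p <- matrix(runif(6), 2, 3)
    expect_gte(total_loss(p, y), 0)
  })
})

test_that("autodiff gradient of the fused loss matches finite differences", {
  withr::with_seed(77, {
    # 3-node fixture with label context and spectral blocks attached
    cfg <- fedgat_config(backbone = list(hidden = c(4L, 4L),
                                         heads = c(2L, 2L, 1L),
                                         head_hidden = 4L))
    C <- 2
    g <- make_graph("fx", path_graph(3), C = C, d = 3,
                    labels = c(1, 0))
    F_flat <- rnorm(4); g_spec <- rnorm(5)
    params <- backbone_init_params(3, C, extra_in = 9, cfg, seed = 2)
    fwd <- function(p) {
      ns <- asNamespace("fedgat")
      ns$ag_reset()
      nodes <- ns$params_to_nodes(p)
      logits <- ns$backbone_forward_node(nodes, g, F_flat, g_spec, cfg)
      loss <- ns$ag_bce_logits(logits, matrix(g$labels, 1))
      list(loss = loss, nodes = nodes)
    }
    r <- fwd(params)
    asNamespace("fedgat")$ag_backward(r$loss)
    grads <- asNamespace("fedgat")$collect_grads(r$nodes)
    eps <- 1e-5
    worst <- 0
    for (nm in names(params)) {
      idx <- seq_len(min(4, length(params[[nm]]))) # spot-check entries
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        ns <- asNamespace("fedgat")
        num <- (ns$ag_value(fwd(pp)$loss) - ns$ag_value(fwd(pm)$loss)) /
          (2 * eps)
        den <- max(abs(num), abs(grads[[nm]][i]), 1e-4)
        worst <- max(worst, abs(grads[[nm]][i] - num) / den)
      }
    }
    expect_lt(worst, 1e-4)
  })
})

test_that("training reduces the classification loss on a small shard", {
  withr::with_seed(91, {
    cfg <- tiny_config(train = list(local_epochs = 5L))
    C <- 2
    graphs <- lapply(1:12, function(i) {
      y <- rbinom(C, 1, 0.5)
      A <- random_sym_adj(5, 0.5)
      X <- matrix(rep(y, each = 5), 5, C) + matrix(rnorm(10, sd = 0.3), 5, C)
      mlgraph(paste0("g", i), A, X, y)
    })
    F_flat <- rnorm(6); g_list <- lapply(graphs, function(g) rnorm(4))
    params <- backbone_init_params(C, C, extra_in = 10, cfg, seed = 3)
    fit <- backbone_train(params, graphs, F_flat, g_list, config = cfg,
                          epochs = 5, seed = 1)
    expect_lt(fit$epoch_losses[5], fit$epoch_losses[1])
    # zero epochs: parameters unchanged
    fit0 <- backbone_train(params, graphs, F_flat, g_list, config = cfg,
                           epochs = 0, seed = 1)
    expect_identical(fit0$params, params)
  })
})
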