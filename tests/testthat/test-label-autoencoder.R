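# The multi-scale attention autoencoder: scorer, attention coefficients,
# attended features, averaged multi-head features, the deterministic
# encoder, and masked-reconstruction training.

zero_scorer <- function(d_h) {
  list(W1a = matrix(0, d_h, d_h), W1b = matrix(0, d_h, d_h),
       b1 = matrix(0, 1, d_h), w2 = matrix(0, d_h, 1),
       b2 = matrix(0, 1, 1))
}

rand_scorer <- function(d_h) {
  list(W1a = matrix(rnorm(d_h^2), d_h, d_h),
       W1b = matrix(rnorm(d_h^2), d_h, d_h),
       b1 = matrix(rnorm(d_h), 1, d_h),
       w2 = matrix(rnorm(d_h), d_h, 1),
       b2 = matrix(rnorm(1), 1, 1))
}

test_that("neural similarity: zero weights give zero, order matters, stable", {
  withr::with_seed(3, {
    d_h <- 4
    zi <- rnorm(d_h); zj <- rnorm(d_h)
    expect_equal(neural_similarity(zero_scorer(d_h), zi, zj), 0)
    sc <- rand_scorer(d_h)
    s_ij <- neural_similarity(sc, zi, zj)
    s_ji <- neural_similarity(sc, zj, zi)
    expect_false(isTRUE(all.equal(s_ij, s_ji))) # asymmetric by construction
    expect_identical(s_ij, neural_similarity(sc, zi, zj)) # deterministic
  })
})

test_that("attention coefficients are a softmax over the neighborhood", {
  expect_equal(attention_coefficients(rep(1.3, 5)), rep(1 / 5, 5))
  expect_equal(attention_coefficients(0.7), 1)
  expect_equal(attention_coefficients(c(log(2), 0)), c(2 / 3, 1 / 3))
  expect_error(attention_coefficients(numeric(0)), "empty neighborhood")
  withr::with_seed(9, {
    for (i in 1:100) {
      a <- attention_coefficients(rnorm(sample(1:10, 1), sd = 3))
      expect_equal(sum(a), 1, tolerance = 1e-12)
      expect_true(all(a > 0))
    }
  })
})

test_that("attend applies value map, coefficients and ReLU", {
  withr::with_seed(13, {
    C <- 4; d <- 3; d_h <- 3
    Lt <- matrix(rnorm(C * d), C, d)
    # identity value map, single neighbor j: f_i = ReLU(l_j)
    expect_equal(attend(1, diag(3), Lt, nbrs = 2), pmax(Lt[2, ], 0))
    # uniform attention, identity V: ReLU of neighborhood mean
    expect_equal(attend(rep(1 / 3, 3), diag(3), Lt, nbrs = c(1, 3, 4)),
                 pmax(colMeans(Lt[c(1, 3, 4), ]), 0))
    # all-nonnegative inputs: ReLU is the identity
    Lp <- abs(Lt); Vp <- diag(3)
    expect_equal(attend(c(0.5, 0.5), Vp, Lp, nbrs = c(1, 2)),
                 colMeans(Lp[1:2, ]))
  })
})

test_that("averaged multi-head attention reduces to single-head at K = 1", {
  withr::with_seed(21, {
    for (i in 1:20) {
      C <- sample(3:8, 1); d <- 4; d_h <- 5
      Lt <- matrix(rnorm(C * d), C, d)
      nbrs <- sample(C, sample(1:C, 1))
      alpha <- attention_coefficients(rnorm(length(nbrs)))
      V <- matrix(rnorm(d * d_h), d, d_h)
      expect_equal(multi_head_feature(list(alpha), list(V), Lt, nbrs),
                   attend(alpha, V, Lt, nbrs))
    }
    # identical heads equal the single head
    C <- 5; Lt <- matrix(rnorm(C * 4), C, 4)
    nbrs <- c(1, 3); alpha <- c(0.7, 0.3); V <- matrix(rnorm(4 * 5), 4, 5)
    expect_equal(
      multi_head_feature(list(alpha, alpha, alpha), list(V, V, V), Lt, nbrs),
      attend(alpha, V, Lt, nbrs))
    # opposite pre-activations cancel to zero
    expect_equal(multi_head_feature(list(alpha, alpha), list(V, -V), Lt, nbrs),
                 rep(0, 5))
  })
})

test_that("reconstruction loss is the per-node summed squared error mean", {
  X <- matrix(c(1, 0), 1, 2)
  expect_equal(reconstruction_loss(X, X * 0), 1.0)
  expect_equal(reconstruction_loss(X, X), 0)
  withr::with_seed(2, {
    A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
    expect_equal(reconstruction_loss(A, A + 2 * (B - A)),
                 4 * reconstruction_loss(A, B))
  })
})

test_that("encoder is deterministic and permutation-equivariant over labels", {
  withr::with_seed(37, {
    C <- 6; d <- 10
    Lt <- matrix(rnorm(C * d), C, d)
    lg <- build_label_graph(Lt)
    params <- ae_init_params(d, 5, heads = 2, scales = 1:3, seed = 4)
    F1 <- ae_encode(params, lg, heads = 2)
    expect_identical(F1, ae_encode(params, lg, heads = 2))
    expect_equal(dim(F1), c(C, 3 * 5))

    # single isolated label: self-loop fallback still yields a finite row
    lg1 <- build_label_graph(matrix(rnorm(d), 1, d))
    F_single <- ae_encode(params, lg1, heads = 2)
    expect_equal(dim(F_single), c(1, 15))
    expect_true(all(is.finite(F_single)))

    # permuting labels permutes the rows of F identically; the attention
    # weights depend only on each label's own embedding and neighborhood
    perm <- sample(C)
    lg_p <- build_label_graph(Lt[perm, , drop = FALSE])
    # guard: the thresholded graph must be the permuted graph for
    # equivariance to be testable
    expect_equal(lg_p$scale_adjacencies[["1"]],
                 lg$scale_adjacencies[["1"]][perm, perm])
    F2 <- ae_encode(params, lg_p, heads = 2)
    expect_equal(F2, F1[perm, , drop = FALSE], tolerance = 1e-10)
  })
})

test_that("training reduces reconstruction loss on a 6-label fixture", {
  withr::with_seed(53, {
    C <- 6; d <- 12
    Lt <- matrix(rnorm(C * d), C, d) * runif(C) # weighted-embedding-like
    lg <- build_label_graph(Lt)
    cfg <- fedgat_config(ae = list(epochs = 120L, hidden_dim = 8L,
                                   heads = 2L, lr = 5e-3))
    fit <- train_autoencoder(lg, cfg, seed = 5)
    expect_length(fit$loss_trace, 120L)
    expect_true(all(is.finite(fit$loss_trace)))
    expect_lt(min(fit$loss_trace), fit$loss_trace[1]) # strict improvement
    # deterministic retrain
    fit2 <- train_autoencoder(lg, cfg, seed = 5)
    expect_identical(fit$loss_trace, fit2$loss_trace)
    expect_identical(fit$F, fit2$F)
  })
})
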