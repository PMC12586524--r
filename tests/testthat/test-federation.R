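# Server-side machinery: similarity matrix, client clustering, grouped
# averaging, gated fusion, and the aggregation identities.

rand_weights <- function(seed = 1) {
  withr::with_seed(seed, list(a = matrix(rnorm(6), 2, 3),
                              b = matrix(rnorm(4), 4, 1)))
}

test_that("similarity matrix is the pairwise cosine with zero-vector rule", {
  g <- rnorm(10)
  S <- similarity_matrix(list(g, g, g))
  expect_equal(S, matrix(1, 3, 3))
  S2 <- similarity_matrix(list(c(1, 0), c(0, 2)))
  expect_equal(S2, diag(2))
  S3 <- similarity_matrix(list(c(1, 1), c(0, 0)))
  expect_equal(S3[2, ], c(0, 0))
  expect_equal(S3[2, 2], 0)
  withr::with_seed(3, {
    vs <- lapply(1:6, function(i) rnorm(8))
    S <- similarity_matrix(vs)
    expect_true(isSymmetric(S))
    expect_true(all(S >= -1 & S <= 1))
    expect_equal(diag(S), rep(1, 6))
  })
  expect_error(similarity_matrix(list(1:2, 1:3)), "mismatch")
})

test_that("clustering recovers block-diagonal structure and edge cases", {
  # two all-ones blocks: compare against the brute-force best 2-partition
  # (maximum total within-block similarity over all 2-colourings)
  S <- matrix(0, 5, 5)
  S[1:2, 1:2] <- 1
  S[3:5, 3:5] <- 1
  brute_best <- function(S) {
    K <- nrow(S); best <- NULL; best_val <- -Inf
    for (code in 0:(2^K - 1)) {
      memb <- as.integer(intToBits(code))[1:K]
      if (length(unique(memb)) < 2) next
      val <- sum(S[outer(memb, memb, "==")])
      if (val > best_val) { best_val <- val; best <- memb }
    }
    best
  }
  oracle <- brute_best(S)
  got <- cluster_clients(S, n_groups = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(got$membership, oracle), 1)
  # all-ones similarity: auto finds a single group
  S1 <- matrix(1, 4, 4)
  expect_length(cluster_clients(S1, "auto")$groups, 1L)
  # n_groups = K: singletons
  gk <- cluster_clients(S, n_groups = 5)
  expect_length(gk$groups, 5L)
  expect_equal(sort(unlist(gk$groups)), 1:5)
  # K = 1: one singleton group
  g1 <- cluster_clients(matrix(1, 1, 1))
  expect_equal(g1$groups, list(1L))
})

test_that("group average is the exact unweighted (or weighted) mean", {
  w1 <- rand_weights(1); w2 <- rand_weights(2)
  m <- group_average(list(w1, w2))
  expect_equal(m$a, (w1$a + w2$a) / 2)
  expect_equal(group_average(list(w1, w1)), w1)
  neg <- lapply(w1, function(x) -x)
  z <- group_average(list(w1, neg))
  expect_equal(z$a, w1$a * 0)
  # permutation invariance
  w3 <- rand_weights(3)
  expect_equal(group_average(list(w1, w2, w3)),
               group_average(list(w3, w1, w2)))
  # sample-size weighting matches the global objective's weights
  mw <- group_average(list(w1, w2), sample_sizes = c(3, 1))
  expect_equal(mw$a, 0.75 * w1$a + 0.25 * w2$a)
  bad <- list(a = matrix(0, 2, 3), b = matrix(0, 2, 1))
  expect_error(group_average(list(w1, bad)), "shape mismatch")
})

test_that("gated fusion weights groups by similarity trace", {
  w1 <- rand_weights(4); w2 <- rand_weights(5)
  ids <- c("a", "b", "c")
  S <- diag(3) * 0 + 0.5; diag(S) <- 1
  asn <- fedgat:::new_groups(list(c("a", "b"), "c"), c(1, 1, 2), S, ids)
  fused <- gated_fusion(list(w1, w2), asn)
  # unit-diagonal S: beta proportional to group sizes |G_p| / K
  expect_equal(fused$beta, c(2 / 3, 1 / 3))
  expect_equal(fused$weights$a, 2 / 3 * w1$a + 1 / 3 * w2$a)
  # one group: fusion is the identity
  asn1 <- fedgat:::new_groups(list(ids), c(1, 1, 1), S, ids)
  expect_equal(gated_fusion(list(w1), asn1)$weights, w1)
  # equal traces: simple average
  asn2 <- fedgat:::new_groups(list(c("a", "b"), c("c", "d")), c(1, 1, 2, 2),
                              rbind(cbind(S[1:2, 1:2], matrix(0, 2, 2)),
                                    cbind(matrix(0, 2, 2), S[1:2, 1:2])),
                              c("a", "b", "c", "d"))
  f2 <- gated_fusion(list(w1, w2), asn2)
  expect_equal(f2$beta, c(0.5, 0.5))
  # random unit-diagonal S: beta_p = |G_p| / K exactly
  withr::with_seed(6, {
    K <- 7
    Sr <- matrix(runif(K * K, -0.5, 0.9), K, K)
    Sr <- (Sr + t(Sr)) / 2; diag(Sr) <- 1
    memb <- sample(1:3, K, replace = TRUE)
    ids <- paste0("c", 1:K)
    groups <- lapply(1:3, function(g) ids[memb == g])
    groups <- groups[lengths(groups) > 0]
    asn <- fedgat:::new_groups(groups, memb, Sr, ids)
    f <- gated_fusion(lapply(seq_along(groups), function(i) rand_weights(i)),
                      asn)
    expect_equal(f$beta, lengths(groups) / K)
    expect_equal(sum(f$beta), 1)
  })
  # all-zero gate mass falls back to uniform with a warning
  S0 <- matrix(0, 2, 2)
  asn0 <- fedgat:::new_groups(list("a", "b"), c(1, 2), S0, c("a", "b"))
  expect_warning(f0 <- gated_fusion(list(w1, w2), asn0), "uniform")
  expect_equal(f0$beta, c(0.5, 0.5))
})

test_that("local training: zero epochs returns the global weights", {
  withr::with_seed(15, {
    ds <- make_tiny_dataset(K = 1, n_graphs = 6, C = 2, seed = 2)
    cfg <- tiny_config(train = list(local_epochs = 0L))
    shard <- ds$shards[[1]]
    st <- fedgat:::client_state(shard, cfg, seed = 3)
    global <- backbone_init_params(
      3, 2, extra_in = length(st$F_flat) + cfg$spectral$N_max * cfg$spectral$M,
      cfg, seed = 1)
    res <- local_train(shard, global, cfg, seed = 3, round = 1, state = st)
    expect_identical(res$report$weights, global)
    expect_false(res$report$failed)
    expect_length(res$report$summary$g_tilde,
                  cfg$spectral$N_max * cfg$spectral$M)
    # identical re-run: identical report
    res2 <- local_train(shard, global, cfg, seed = 3, round = 1, state = st)
    expect_identical(res2$report$summary$g_tilde, res$report$summary$g_tilde)
  })
})

test_that("aggregation identities: one group equals FedAvg; asyagg ablation", {
  withr::with_seed(25, {
    reports <- lapply(1:4, function(k) {
      list(client_id = paste0("c", k), weights = rand_weights(k),
           summary = privatize(rep(1, 10), epsilon = 1e12, delta_f = 1,
                               seed = k),
           n_samples = 5, round = 1, train_loss = 1, failed = FALSE)
    })
    cfg <- fedgat_config(federation = list(n_groups = 1))
    agg <- fedgat:::aggregate_reports(reports, cfg, seed = 1)
    fedavg <- group_average(lapply(reports, `[[`, "weights"))
    expect_equal(agg$weights$a, fedavg$a, tolerance = 1e-10)
    expect_equal(agg$weights$b, fedavg$b, tolerance = 1e-10)
    # identical summaries, noiseless: grouped path equals plain FedAvg
    cfg_auto <- fedgat_config(federation = list(n_groups = "auto"))
    agg2 <- fedgat:::aggregate_reports(reports, cfg_auto, seed = 1)
    expect_equal(agg2$weights$a, fedavg$a, tolerance = 1e-10)
    # asyagg ablation: sample-weighted FedAvg over all reports
    cfg_abl <- fedgat_config(ablate = list(asyagg = TRUE))
    reports[[1]]$n_samples <- 15
    agg3 <- fedgat:::aggregate_reports(reports, cfg_abl, seed = 1)
    manual <- group_average(lapply(reports, `[[`, "weights"),
                            sample_sizes = c(15, 5, 5, 5))
    expect_equal(agg3$weights, manual)
    expect_equal(agg3$n_groups, 1L)
    # failed reports are excluded
    reports[[2]]$failed <- TRUE
    agg4 <- fedgat:::aggregate_reports(reports, cfg_abl, seed = 1)
    manual4 <- group_average(lapply(reports[-2], `[[`, "weights"),
                             sample_sizes = c(15, 5, 5))
    expect_equal(agg4$weights, manual4)
  })
})

test_that("the round loop is reproducible and records history", {
  ds <- make_tiny_dataset(K = 2, n_graphs = 8, C = 2, seed = 9)
  cfg <- tiny_config()
  r1 <- run_federation(ds, cfg, seed = 21)
  r2 <- run_federation(ds, cfg, seed = 21)
  expect_identical(r1$history$auc_macro, r2$history$auc_macro)
  expect_identical(r1$global_weights, r2$global_weights)
  expect_equal(nrow(r1$history), 2L)
  expect_true(all(c("round", "n_groups", "beta", "train_loss",
                    "auc_macro") %in% names(r1$history)))
  # K = 1: global equals the single client's trained weights each round
  ds1 <- make_tiny_dataset(K = 1, n_graphs = 8, C = 2, seed = 10)
  run1 <- run_federation(ds1, cfg, seed = 5)
  st <- fedgat:::client_state(ds1$shards[[1]], cfg, seed = 5)
  # reproduce round 1 manually from the same initial weights
  d_x <- ncol(ds1$shards[[1]]$graphs[[1]]$node_features)
  g_len <- cfg$spectral$N_max * cfg$spectral$M
  global0 <- backbone_init_params(
    d_x, 2, extra_in = length(st$F_flat) + g_len, cfg,
    seed = fedgat:::derive_seed(5, "init"))
  res <- local_train(ds1$shards[[1]], global0, cfg, seed = 5, round = 1,
                     state = st)
  fit2 <- backbone_train(res$report$weights, st$train_graphs, st$F_flat,
                         st$g_train, ae_loss = st$ae_loss, config = cfg,
                         seed = fedgat:::derive_seed(5, "train", 2,
                                                     st$client_id))
  expect_equal(run1$global_weights, fit2$params, tolerance = 1e-12)
})

test_that("async mode runs to completion and stays reproducible", {
  ds <- make_tiny_dataset(K = 3, n_graphs = 6, C = 2, seed = 12)
  cfg <- tiny_config(federation = list(mode = "async", rounds = 3L,
                                       max_delay = 2L))
  a1 <- run_federation(ds, cfg, seed = 8)
  a2 <- run_federation(ds, cfg, seed = 8)
  expect_identical(a1$history$train_loss, a2$history$train_loss)
  expect_equal(nrow(a1$history), 3L)
})

test_that("tidy, glance and autoplot work on run objects", {
  ds <- make_tiny_dataset(K = 2, n_graphs = 6, C = 2, seed = 30)
  run <- run_federation(ds, tiny_config(), seed = 2)
  td <- tidy(run)
  expect_true(all(c("round", "metric", "value") %in% names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$auc_macro >= 0 && gl$auc_macro <= 1)
  p <- ggplot2::autoplot(run)
  expect_s3_class(p, "ggplot")
  ev <- run$final_eval
  expect_s3_class(tidy(ev), "tbl_df")
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
})
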