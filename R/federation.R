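# The federated engine: per-client local training (label semantics ->
# autoencoder -> backbone), transmission of weights plus a privatised
# spectral summary, server-side cosine-similarity clustering of clients,
# within-group federated averaging, trace-gated inter-group fusion, and
# the synchronous / simulated-clock asynchronous round loop.

#' Cosine similarity matrix between client spectral summaries
#'
#' `S[i, j] = (g_i . g_j) / (|g_i| |g_j|)`; any all-zero summary gets a
#' zero row/column (including its diagonal).
#'
#' @param summaries List of equal-length numeric vectors (or
#'   `fedgat_private_summary` objects).
#' @return K x K symmetric matrix.
#' @export
similarity_matrix <- function(summaries) {
  vecs <- lapply(summaries, function(s) {
    if (inherits(s, "fedgat_private_summary")) s$g_tilde else as.numeric(s)
  })
  lens <- vapply(vecs, length, integer(1))
  if (length(unique(lens)) != 1L) stop("summary length mismatch")
  cosine_matrix(do.call(rbind, vecs))
}

#' Group clients by spectral clustering of the similarity matrix
#'
#' With `n_groups = "auto"` the group count is chosen by the largest
#' eigengap of the symmetric-normalised Laplacian of the nonnegative
#' part of `S`, capped at `ceiling(K/2)`. The partition itself comes
#' from k-means on the kernel-PCA embedding of `S` (eigenvectors of the
#' double-centred similarity matrix): double-centring removes the
#' common similarity component every pair of clients shares, which
#' otherwise dominates the cosine geometry and masks weak group
#' structure.
#'
#' @param S K x K similarity matrix.
#' @param n_groups Integer group count or `"auto"`.
#' @param client_ids Optional identifiers (default `1:K`).
#' @param seed Seed for the k-means restarts.
#' @return A `fedgat_groups` object: `groups` (list of member id
#'   vectors), `membership` (integer vector), `similarity` (S).
#' @export
cluster_clients <- function(S, n_groups = "auto", client_ids = NULL,
                            seed = 1L) {
  S <- as.matrix(S)
  K <- nrow(S)
  client_ids <- client_ids %||% seq_len(K)
  if (K == 1L) {
    return(new_groups(list(client_ids), 1L, S, client_ids))
  }
  cap <- max(1L, ceiling(K / 2))
  if (identical(n_groups, "auto")) {
    W <- pmax(S, 0)
    diag(W) <- 1
    dinv <- 1 / sqrt(pmax(rowSums(W), 1e-12))
    Lsym <- diag(K) - (dinv * W) %*% diag(dinv)
    lambda <- rev(eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values) # ascending
    gaps <- diff(lambda)[seq_len(min(cap, K - 1L))]
    n_groups <- which.max(gaps)
  }
  n_groups <- as.integer(n_groups)
  if (n_groups >= K) {
    return(new_groups(as.list(client_ids), seq_len(K), S, client_ids))
  }
  if (n_groups <= 1L) {
    return(new_groups(list(client_ids), rep(1L, K), S, client_ids))
  }
  # kernel-PCA embedding of the double-centred similarity matrix
  H <- diag(K) - matrix(1 / K, K, K)
  Sc <- H %*% ((S + t(S)) / 2) %*% H
  ev <- eigen((Sc + t(Sc)) / 2, symmetric = TRUE)
  r <- max(1L, n_groups - 1L)
  U <- ev$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(r)], 0)), r)
  memb <- if (max(abs(U)) < 1e-12) {
    # degenerate: all clients indistinguishable, fill groups round-robin
    rep_len(seq_len(n_groups), K)
  } else {
    with_seed(seed, stats::kmeans(U, centers = n_groups,
                                  nstart = 20L)$cluster)
  }
  groups <- lapply(sort(unique(memb)), function(g) client_ids[memb == g])
  new_groups(groups, memb, S, client_ids)
}

new_groups <- function(groups, membership, S, client_ids) {
  structure(list(groups = groups, membership = as.integer(membership),
                 similarity = S, client_ids = client_ids),
            class = "fedgat_groups")
}

#' @export
print.fedgat_groups <- function(x, ...) {
  cat("<fedgat_groups>", length(x$groups), "group(s):\n")
  for (i in seq_along(x$groups)) {
    cat("  G", i, ": ", paste(x$groups[[i]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Within-group federated average
#'
#' Unweighted mean of the member weight collections; `sample_sizes`
#' switches to sample-size
#' weighting (matching the global objective's `M^i / |M|` weights).
#'
#' @param weight_list Nonempty list of weight collections.
#' @param sample_sizes Optional numeric vector of member sample counts.
#' @return A weight collection.
#' @export
group_average <- function(weight_list, sample_sizes = NULL) {
  if (length(weight_list) == 0L) stop("empty group")
  for (w in weight_list[-1]) check_signature(weight_list[[1]], w)
  if (is.null(sample_sizes)) {
    coef <- rep(1 / length(weight_list), length(weight_list))
  } else {
    stopifnot(length(sample_sizes) == length(weight_list))
    coef <- sample_sizes / sum(sample_sizes)
  }
  out <- weights_zero_like(weight_list[[1]])
  for (i in seq_along(weight_list)) {
    out <- weights_add(out, weights_scale(weight_list[[i]], coef[i]))
  }
  out
}

#' Trace-gated fusion of group models
#'
#' `W_global = sum_p beta_p W_Gp` with
#' `beta_p = trace(S_Gp) / sum_q trace(S_Gq)` where `S_Gp` is the
#' intra-group similarity submatrix. With a unit-diagonal S this makes
#' `beta_p` proportional to group size. `gating = "offdiag_mean"` uses
#' the mean off-diagonal similarity instead (1 for singletons). If all
#' gate masses are zero, uniform weights are used with a warning.
#'
#' @param group_models List of weight collections, one per group.
#' @param assignment A `fedgat_groups` object.
#' @param gating `"trace"` (the default) or `"offdiag_mean"`.
#' @return List with `weights` (the fused collection) and `beta`.
#' @export
gated_fusion <- function(group_models, assignment,
                         gating = c("trace", "offdiag_mean")) {
  gating <- match.arg(gating)
  groups <- assignment$groups
  stopifnot(length(group_models) == length(groups))
  S <- assignment$similarity
  ids <- assignment$client_ids
  mass <- vapply(seq_along(groups), function(p) {
    idx <- match(groups[[p]], ids)
    Sg <- S[idx, idx, drop = FALSE]
    if (gating == "trace") {
      sum(diag(Sg))
    } else if (length(idx) == 1L) {
      1
    } else {
      mean(Sg[upper.tri(Sg) | lower.tri(Sg)])
    }
  }, numeric(1))
  if (sum(mass) <= 0) {
    warning("all gate masses are zero; falling back to uniform fusion")
    beta <- rep(1 / length(groups), length(groups))
  } else {
    beta <- mass / sum(mass)
  }
  fused <- weights_zero_like(group_models[[1]])
  for (p in seq_along(group_models)) {
    fused <- weights_add(fused, weights_scale(group_models[[p]], beta[p]))
  }
  list(weights = fused, beta = beta)
}

# ---- client-side ---------------------------------------------------------

# Per-client cached state: train/test split, label semantics, trained
# autoencoder (F and final reconstruction loss), per-graph spectral
# features. Everything that does not change across rounds.
client_state <- function(shard, config, seed) {
  n <- length(shard$graphs)
  test_frac <- config$federation$test_frac
  n_test <- if (test_frac > 0 && n > 1L) max(1L, round(test_frac * n)) else 0L
  idx <- with_seed(derive_seed(seed, "split", shard$client_id),
                   sample.int(n))
  test_idx <- sort(idx[seq_len(n_test)])
  train_idx <- sort(setdiff(seq_len(n), test_idx))
  train_graphs <- shard$graphs[train_idx]
  sem <- label_semantics(shard_subset(shard, train_idx), config)
  ae <- train_autoencoder(sem$label_graph, config,
                          seed = derive_seed(seed, "ae", shard$client_id))
  scfg <- config$spectral
  g_all <- lapply(shard$graphs, graph_spectral_feature,
                  M = scfg$M, N_max = scfg$N_max)
  list(
    client_id = shard$client_id,
    train_idx = train_idx, test_idx = test_idx,
    train_graphs = train_graphs,
    test_graphs = shard$graphs[test_idx],
    semantics = sem,
    F_flat = as.vector(t(ae$F)),
    ae_loss = ae$loss_trace[length(ae$loss_trace)],
    g_train = g_all[train_idx],
    g_test = g_all[test_idx],
    raw_summary = client_spectral_summary(g_all[train_idx]),
    n_samples = length(train_idx)
  )
}

shard_subset <- function(shard, idx) {
  client_shard(shard$client_id, shard$graphs[idx], shard$label_space)
}

#' Local training step for one client
#'
#' Runs the per-client pipeline from the current global weights: the
#' label-semantics stage and autoencoder are computed once and cached in
#' `state`; each call trains the backbone for the configured local
#' epochs and privatises the client's mean spectral summary (noise
#' re-drawn per transmission). Divergence (non-finite loss) yields a
#' report flagged `failed` that aggregation excludes.
#'
#' @param shard A `fedgat_shard`.
#' @param global_weights Weight collection to start from.
#' @param config A [fedgat_config()].
#' @param seed Integer seed.
#' @param round Round number (mixed into sub-seeds).
#' @param state Cached state from a previous call (or `NULL`).
#' @return List with `report` (client_id, weights, summary, n_samples,
#'   round, train_loss, failed) and `state`.
#' @export
local_train <- function(shard, global_weights, config = fedgat_config(),
                        seed = 1L, round = 1L, state = NULL) {
  if (is.null(state)) state <- client_state(shard, config, seed)
  scfg <- config$spectral
  summary <- privatize(state$raw_summary, epsilon = scfg$epsilon,
                       delta_f = scfg$delta_f,
                       n_graphs = state$n_samples, M = scfg$M,
                       seed = derive_seed(seed, "dp", round,
                                          state$client_id))
  fit <- tryCatch(
    backbone_train(global_weights, state$train_graphs, state$F_flat,
                   state$g_train, ae_loss = state$ae_loss, config = config,
                   seed = derive_seed(seed, "train", round,
                                      state$client_id)),
    error = function(e) e)
  failed <- inherits(fit, "error")
  report <- list(
    client_id = state$client_id,
    weights = if (failed) global_weights else fit$params,
    summary = summary,
    n_samples = state$n_samples,
    round = round,
    train_loss = if (failed) NA_real_ else
      fit$epoch_losses[length(fit$epoch_losses)] %||% NA_real_,
    failed = failed
  )
  if (failed) {
    warning("client ", state$client_id, " failed in round ", round, ": ",
            conditionMessage(fit))
  }
  list(report = report, state = state)
}

# ---- server-side aggregation --------------------------------------------

# One aggregation pass over a set of client reports. Returns the new
# global weights plus the grouping diagnostics.
aggregate_reports <- function(reports, config, seed = 1L) {
  ok <- Filter(function(r) !isTRUE(r$failed), reports)
  if (length(ok) == 0L) return(NULL)
  n_samp <- vapply(ok, function(r) r$n_samples, numeric(1))
  if (isTRUE(config$ablate$asyagg)) {
    # ablated server: plain sample-weighted federated averaging
    w <- group_average(lapply(ok, function(r) r$weights),
                       sample_sizes = n_samp)
    return(list(weights = w, beta = 1,
                groups = list(vapply(ok, function(r) r$client_id,
                                     character(1))),
                n_groups = 1L))
  }
  S <- similarity_matrix(lapply(ok, function(r) r$summary))
  ids <- vapply(ok, function(r) r$client_id, character(1))
  assignment <- cluster_clients(S, n_groups = config$federation$n_groups,
                                client_ids = ids, seed = seed)
  sizes <- if (isTRUE(config$federation$weighted_fedavg)) n_samp else NULL
  group_models <- lapply(assignment$groups, function(members) {
    idx <- match(members, ids)
    group_average(lapply(ok[idx], function(r) r$weights),
                  sample_sizes = sizes[idx])
  })
  fused <- gated_fusion(group_models, assignment,
                        gating = config$federation$gating)
  list(weights = fused$weights, beta = fused$beta,
       groups = assignment$groups, n_groups = length(assignment$groups))
}

# ---- the round loop ------------------------------------------------------

#' Run the federated simulation
#'
#' Builds per-client state (split, label semantics, autoencoder, spectral
#' features), then iterates communication rounds: local training on every
#' client from the current global weights, transmission of weights plus a
#' freshly privatised spectral summary, server-side similarity grouping,
#' within-group averaging and gated fusion. In `"async"` mode each
#' client's report is delayed by a per-round draw on a simulated clock; a
#' group's model refreshes when all its members' reports have arrived and
#' fusion re-runs with the latest model of every group. Evaluation on the
#' held-out test graphs (pooled over clients, each scored with its own
#' label context) every `eval_every` rounds.
#'
#' @param dataset A `fedgat_dataset`.
#' @param config A [fedgat_config()].
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param verbose Log per-round progress.
#' @return A `fedgat_run` object: `history` (tibble, one row per round),
#'   `global_weights`, `final_eval`, `config`, `client_states`.
#' @export
run_federation <- function(dataset, config = fedgat_config(), seed = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(dataset, "fedgat_dataset"))
  K <- dataset$K
  C <- dataset$label_space$C
  states <- lapply(dataset$shards, client_state, config = config,
                   seed = seed)
  d_x <- ncol(dataset$shards[[1]]$graphs[[1]]$node_features)
  g_len <- config$spectral$N_max * config$spectral$M
  extra_in <- length(states[[1]]$F_flat) + g_len
  global <- backbone_init_params(d_x, C, extra_in, config,
                                 seed = derive_seed(seed, "init"))
  rounds <- config$federation$rounds
  async <- identical(config$federation$mode, "async")
  pending <- list() # async: reports awaiting arrival
  latest_group_models <- NULL
  history <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    reports <- vector("list", K)
    for (k in seq_len(K)) {
      res <- local_train(dataset$shards[[k]], global, config,
                         seed = seed, round = r, state = states[[k]])
      states[[k]] <- res$state
      reports[[k]] <- res$report
    }
    if (async) {
      for (k in seq_len(K)) {
        delay <- with_seed(derive_seed(seed, "delay", r, k),
                           sample.int(config$federation$max_delay, 1L))
        reports[[k]]$arrival_time <- r + delay - 1L
        pending[[length(pending) + 1L]] <- reports[[k]]
      }
      arrived <- Filter(function(p) p$arrival_time <= r, pending)
      pending <- Filter(function(p) p$arrival_time > r, pending)
      # keep only the freshest report per client
      agg_in <- latest_per_client(arrived)
    } else {
      agg_in <- reports
    }
    agg <- if (length(agg_in) > 0L) {
      aggregate_reports(agg_in, config,
                        seed = derive_seed(seed, "cluster", r))
    }
    if (is.null(agg)) {
      fg_log("round ", r, ": no successful reports; round skipped",
             verbose = verbose)
      history[[r]] <- round_row(r, reports, NULL, NA_real_, NULL)
      next
    }
    global <- agg$weights
    ev <- NULL
    if (r %% config$federation$eval_every == 0L || r == rounds) {
      ev <- evaluate_global(global, states, config)
    }
    history[[r]] <- round_row(r, reports, agg,
                              mean(vapply(reports, function(x)
                                x$train_loss, numeric(1)), na.rm = TRUE),
                              ev)
    fg_log("round ", r, "/", rounds, ": groups = ", agg$n_groups,
           if (!is.null(ev)) paste0(", macro AUC = ",
                                    signif(ev$auc_macro, 4)),
           verbose = verbose)
  }
  final_eval <- evaluate_global(global, states, config)
  structure(list(history = dplyr::bind_rows(history),
                 global_weights = global,
                 final_eval = final_eval,
                 config = config,
                 client_states = states),
            class = "fedgat_run")
}

latest_per_client <- function(reports) {
  if (length(reports) == 0L) return(list())
  ids <- vapply(reports, function(r) r$client_id, character(1))
  rounds <- vapply(reports, function(r) r$round, numeric(1))
  keep <- vapply(unique(ids), function(id) {
    cand <- which(ids == id)
    cand[which.max(rounds[cand])]
  }, integer(1))
  reports[keep]
}

round_row <- function(r, reports, agg, train_loss, ev) {
  tibble::tibble(
    round = r,
    n_reports = sum(!vapply(reports, function(x) isTRUE(x$failed),
                            logical(1))),
    n_groups = if (is.null(agg)) NA_integer_ else agg$n_groups,
    groups = list(if (is.null(agg)) NULL else agg$groups),
    beta = list(if (is.null(agg)) NULL else agg$beta),
    train_loss = train_loss,
    auc_macro = if (is.null(ev)) NA_real_ else ev$auc_macro,
    cf1 = if (is.null(ev)) NA_real_ else ev$cf1,
    of1 = if (is.null(ev)) NA_real_ else ev$of1,
    map = if (is.null(ev)) NA_real_ else ev$map
  )
}

# Score every client's held-out graphs with the global weights and that
# client's own label context; pool scores and truths for the metrics.
evaluate_global <- function(global, states, config) {
  scores <- list(); truths <- list()
  for (st in states) {
    if (length(st$test_graphs) == 0L) next
    p <- backbone_predict(global, st$test_graphs, st$F_flat, st$g_test,
                          config)
    scores[[length(scores) + 1L]] <- p
    truths[[length(truths) + 1L]] <-
      do.call(rbind, lapply(st$test_graphs, function(g) g$labels))
  }
  if (length(scores) == 0L) return(NULL)
  evaluate_predictions(do.call(rbind, scores), do.call(rbind, truths))
}

#' @export
print.fedgat_run <- function(x, ...) {
  cat("<fedgat_run>", nrow(x$history), "rounds\n")
  if (!is.null(x$final_eval)) {
    cat("  final macro AUC:", signif(x$final_eval$auc_macro, 4),
        " O-F1:", signif(x$final_eval$of1, 4), "\n")
  }
  invisible(x)
}
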