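# Synthetic federated multi-label graph data. Clients are assigned
# round-robin to planted structural groups, each with its own
# random-graph family; labels come from structural predicates flipped
# with small probability; per-client label prevalences are tilted toward
# a Dirichlet draw by rejection over candidate graphs (so labels stay
# consistent with structure); node features carry a linear projection of
# the label vector plus Gaussian noise, giving a learnable
# structure-to-label signal.

#' Specification for the synthetic generator
#'
#' The defaults define the package's reference study conditions: 8
#' clients split over two structural families (Erdos-Renyi p = 0.3 vs
#' Barabasi-Albert m = 2), 60 graphs per client with 12-24 nodes, 6
#' labels, Dirichlet concentration 0.3 (strong label skew), flip rate
#' 0.1 and feature noise 0.5.
#'
#' @param K Number of clients.
#' @param n_structural_groups Planted structural groups (<= K).
#' @param families List of per-group family specs; each a list with
#'   `family` in `"er"`, `"ba"`, `"ws"` and its parameters (`p`; `m`;
#'   `k`, `beta`).
#' @param graphs_per_client Graphs per client.
#' @param nodes_range Inclusive integer range of graph sizes.
#' @param C Number of labels.
#' @param dirichlet_alpha Label-skew concentration (small = skewed).
#' @param flip_rate Per-label Bernoulli flip probability in [0, 0.5).
#' @param feature_noise Gaussian noise sd on node features.
#' @param feature_dim Node feature dimension.
#' @param label_rules Optional list of C predicate functions
#'   `stats -> logical` (see [graph_structure_stats()]); default rules
#'   are built with [default_label_rules()].
#' @param max_attempts Rejection attempts per graph slot before the tilt
#'   is relaxed.
#' @return A `fedgat_synthetic_spec`.
#' @export
synthetic_spec <- function(K = 8L,
                           n_structural_groups = 2L,
                           families = list(list(family = "er", p = 0.3),
                                           list(family = "ba", m = 2)),
                           graphs_per_client = 60L,
                           nodes_range = c(12L, 24L),
                           C = 6L,
                           dirichlet_alpha = 0.3,
                           flip_rate = 0.1,
                           feature_noise = 0.5,
                           feature_dim = 8L,
                           label_rules = NULL,
                           max_attempts = 50L) {
  stopifnot(K >= n_structural_groups, n_structural_groups >= 1L,
            length(families) == n_structural_groups,
            flip_rate >= 0, flip_rate < 0.5,
            nodes_range[1] >= 3L, nodes_range[2] >= nodes_range[1])
  structure(list(K = as.integer(K),
                 n_structural_groups = as.integer(n_structural_groups),
                 families = families,
                 graphs_per_client = as.integer(graphs_per_client),
                 nodes_range = as.integer(nodes_range),
                 C = as.integer(C),
                 dirichlet_alpha = dirichlet_alpha,
                 flip_rate = flip_rate,
                 feature_noise = feature_noise,
                 feature_dim = as.integer(feature_dim),
                 label_rules = label_rules %||% default_label_rules(C),
                 max_attempts = as.integer(max_attempts)),
            class = "fedgat_synthetic_spec")
}

#' Structural statistics of one graph
#'
#' The quantities the default label predicates read.
#'
#' @param A Adjacency matrix.
#' @return List: `n`, `n_edges`, `mean_degree`, `max_degree`, `density`,
#'   `triangles`, `transitivity`.
#' @export
graph_structure_stats <- function(A) {
  n <- nrow(A)
  B <- (A != 0) * 1
  deg <- rowSums(B)
  tri <- sum(diag(B %*% B %*% B)) / 6
  paths2 <- sum(deg * (deg - 1)) / 2
  list(n = n,
       n_edges = sum(B) / 2,
       mean_degree = mean(deg),
       max_degree = max(deg),
       density = if (n > 1) sum(B) / (n * (n - 1)) else 0,
       triangles = tri,
       transitivity = if (paths2 > 0) 3 * tri / paths2 else 0)
}

#' Default structural label predicates
#'
#' Six base predicates over [graph_structure_stats()] (mean degree,
#' triangle count, hub degree, density, transitivity, size), recycled
#' with shifted thresholds when `C > 6`.
#'
#' @param C Number of labels.
#' @return List of C functions `stats -> logical`.
#' @export
default_label_rules <- function(C) {
  # thresholds centred so each predicate fires on roughly half of the
  # denser (Erdos-Renyi p = 0.3) family at the default size range
  base <- list(
    function(s, t) s$mean_degree > 5 + t,
    function(s, t) s$triangles >= 18 * (1 + t / 4),
    function(s, t) s$max_degree >= 9 + t,
    function(s, t) s$density > 0.30 + 0.03 * t,
    function(s, t) s$transitivity > 0.29 + 0.03 * t,
    function(s, t) s$n > 17 + t
  )
  lapply(seq_len(C), function(k) {
    f <- base[[(k - 1L) %% 6L + 1L]]
    shift <- (k - 1L) %/% 6L
    function(s) isTRUE(f(s, shift))
  })
}

sample_family_graph <- function(fam, n) {
  g <- switch(fam$family,
    er = igraph::sample_gnp(n, fam$p),
    ba = igraph::sample_pa(n, m = fam$m, directed = FALSE),
    ws = igraph::sample_smallworld(1, n, fam$k, fam$beta),
    stop("unknown graph family: ", fam$family))
  g <- igraph::simplify(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- (A != 0) * 1
  diag(A) <- 0
  A
}

#' Generate a synthetic federated dataset
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the same (spec, seed) pair always yields an
#'   identical dataset and manifest.
#' @param verbose Log rejection-relaxation warnings.
#' @return List with `dataset` (a `fedgat_dataset`) and `manifest` (a
#'   list with the planted group assignment, per-client Dirichlet tilts,
#'   empirical prevalences and relaxation counts).
#' @export
generate_synthetic <- function(spec, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "fedgat_synthetic_spec"))
  space <- label_space(sprintf("L%02d", seq_len(spec$C)))
  # global structure-to-feature projection, fixed per dataset
  P <- with_seed(derive_seed(seed, "proj"),
                 matrix(stats::rnorm(spec$feature_dim * spec$C,
                                     sd = 1 / sqrt(spec$C)),
                        spec$feature_dim, spec$C))
  group_of <- ((seq_len(spec$K) - 1L) %% spec$n_structural_groups) + 1L
  shards <- vector("list", spec$K)
  tilts <- matrix(NA_real_, spec$K, spec$C)
  prevalences <- matrix(NA_real_, spec$K, spec$C)
  relaxed <- integer(spec$K)
  for (k in seq_len(spec$K)) {
    res <- with_seed(derive_seed(seed, "client", k), {
      generate_client(spec, k, group_of[k], P)
    })
    shards[[k]] <- client_shard(sprintf("client%02d", k), res$graphs, space)
    tilts[k, ] <- res$tilt
    prevalences[k, ] <- res$prevalence
    relaxed[k] <- res$relaxed
    if (res$relaxed > 0) {
      fg_log("client ", k, ": tilt relaxed on ", res$relaxed,
             " of ", spec$graphs_per_client, " graphs", verbose = verbose)
    }
  }
  manifest <- list(
    seed = seed,
    group_assignment = group_of,
    families = vapply(spec$families, function(f) f$family, character(1)),
    tilts = tilts,
    prevalences = prevalences,
    relaxed = relaxed,
    label_names = space$names
  )
  list(dataset = federated_dataset(shards, space), manifest = manifest)
}

generate_client <- function(spec, k, group, P) {
  fam <- spec$families[[group]]
  tilt <- stats::rgamma(spec$C, shape = spec$dirichlet_alpha)
  if (sum(tilt) == 0) tilt <- rep(1, spec$C)
  tilt <- tilt / sum(tilt)
  delta <- 0.05
  draw_labelled <- function() {
    n <- sample(spec$nodes_range[1]:spec$nodes_range[2], 1L)
    A <- sample_family_graph(fam, n)
    st <- graph_structure_stats(A)
    y0 <- vapply(spec$label_rules, function(rule) as.numeric(rule(st)),
                 numeric(1))
    flips <- stats::runif(spec$C) < spec$flip_rate
    list(A = A, y = abs(y0 - as.numeric(flips)))
  }
  # acceptance tilts relative to the uniform label distribution, so a
  # near-uniform Dirichlet draw (large alpha) accepts every candidate at
  # the same rate and adds no distortion beyond sampling noise
  q <- rep(1 / spec$C, spec$C)
  ratio <- function(y) ((sum(tilt * y) + delta) / (sum(q * y) + delta))^2
  r_hi <- max(1, ((max(tilt) + delta) / (min(q) + delta))^2)
  graphs <- vector("list", spec$graphs_per_client)
  Y <- matrix(0, spec$graphs_per_client, spec$C)
  relaxed <- 0L
  for (i in seq_len(spec$graphs_per_client)) {
    accepted <- FALSE
    for (attempt in seq_len(spec$max_attempts)) {
      cand <- draw_labelled()
      A <- cand$A; y <- cand$y; n <- nrow(A)
      if (stats::runif(1) < min(1, ratio(y) / r_hi)) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) relaxed <- relaxed + 1L
    X <- tcrossprod(rep(1, n), as.numeric(P %*% y)) +
      matrix(stats::rnorm(n * spec$feature_dim, sd = spec$feature_noise),
             n, spec$feature_dim)
    graphs[[i]] <- mlgraph(sprintf("c%02d_g%03d", k, i), A, X, y)
    Y[i, ] <- y
  }
  list(graphs = graphs, tilt = tilt, prevalence = colMeans(Y),
       relaxed = relaxed)
}

#' Per-client empirical label prevalence table
#'
#' @param ds A `fedgat_dataset`.
#' @return A tibble: `client_id` plus one prevalence column per label.
#' @export
prevalence_report <- function(ds) {
  stopifnot(inherits(ds, "fedgat_dataset"))
  rows <- lapply(ds$shards, function(s) {
    Y <- do.call(rbind, lapply(s$graphs, function(g) g$labels))
    prev <- colMeans(Y)
    names(prev) <- ds$label_space$names
    dplyr::bind_cols(tibble::tibble(client_id = s$client_id),
                     tibble::as_tibble(as.list(prev)))
  })
  dplyr::bind_rows(rows)
}
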