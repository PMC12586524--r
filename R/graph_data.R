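# Core data model: attributed multi-label graphs, per-client shards, and
# the federated dataset container, plus readers/writers for the JSON-lines
# interchange format and an optional molecular (SMILES) CSV loader.

#' Construct a label space
#'
#' The ordered set of class names shared by every client and the server.
#' The order is fixed for the whole federation: label vectors, frequency
#' vectors and label embeddings are all indexed by it.
#'
#' @param names Character vector of unique label names.
#' @return A `fedgat_label_space` object with elements `names` and `C`.
#' @export
label_space <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) stop("label space must have at least one label")
  if (anyDuplicated(names)) stop("label names must be unique")
  structure(list(names = names, C = length(names)),
            class = "fedgat_label_space")
}

#' Construct one attributed multi-label graph
#'
#' @param graph_id Identifier string.
#' @param adjacency Symmetric nonnegative n x n matrix with zero diagonal.
#' @param node_features n x d numeric matrix of node attributes.
#' @param labels Binary vector of length C over the shared label space.
#' @return A `fedgat_graph` object.
#' @export
mlgraph <- function(graph_id, adjacency, node_features, labels) {
  adjacency <- as.matrix(adjacency)
  node_features <- as.matrix(node_features)
  n <- nrow(adjacency)
  if (n < 1L) stop("graph must have at least one node")
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (!isSymmetric(unname(adjacency), tol = 1e-12)) {
    stop("adjacency must be symmetric")
  }
  if (any(diag(adjacency) != 0)) stop("adjacency must have zero diagonal")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  if (nrow(node_features) != n) {
    stop("node_features must have one row per node")
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  structure(list(graph_id = as.character(graph_id),
                 adjacency = unname(adjacency),
                 node_features = unname(node_features),
                 labels = labels),
            class = "fedgat_graph")
}

#' Construct a client shard
#'
#' @param client_id Identifier string.
#' @param graphs Nonempty list of [mlgraph()] objects.
#' @param space The shared [label_space()].
#' @return A `fedgat_shard` object.
#' @export
client_shard <- function(client_id, graphs, space) {
  stopifnot(inherits(space, "fedgat_label_space"))
  if (length(graphs) < 1L) stop("shard '", client_id, "' has no graphs")
  bad <- vapply(graphs, function(g) length(g$labels) != space$C, logical(1))
  if (any(bad)) {
    stop("shard '", client_id, "': label vector length != C for graph(s) ",
         paste(which(bad), collapse = ", "))
  }
  structure(list(client_id = as.character(client_id),
                 graphs = graphs, label_space = space),
            class = "fedgat_shard")
}

#' Construct a federated dataset
#'
#' @param shards Nonempty list of [client_shard()] objects sharing one
#'   label space.
#' @param space The shared [label_space()].
#' @return A `fedgat_dataset` object with `K` clients.
#' @export
federated_dataset <- function(shards, space) {
  stopifnot(inherits(space, "fedgat_label_space"))
  if (length(shards) < 1L) stop("dataset must contain at least one client")
  ids <- vapply(shards, function(s) s$client_id, character(1))
  if (anyDuplicated(ids)) stop("client ids must be unique")
  same <- vapply(shards, function(s)
    identical(s$label_space$names, space$names), logical(1))
  if (!all(same)) stop("all shards must share the dataset label space")
  structure(list(shards = shards, label_space = space, K = length(shards)),
            class = "fedgat_dataset")
}

#' @export
print.fedgat_dataset <- function(x, ...) {
  sizes <- vapply(x$shards, function(s) length(s$graphs), integer(1))
  cat("<fedgat_dataset> K =", x$K, "clients, C =", x$label_space$C,
      "labels,", sum(sizes), "graphs\n")
  cat("  shard sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Shard sizes
#'
#' Number of graphs per client and in total.
#'
#' @param ds A `fedgat_dataset`.
#' @return A tibble with columns `client_id` and `n_graphs`.
#' @export
shard_sizes <- function(ds) {
  tibble::tibble(
    client_id = vapply(ds$shards, function(s) s$client_id, character(1)),
    n_graphs = vapply(ds$shards, function(s) length(s$graphs), integer(1))
  )
}

# ---- JSON-lines container -------------------------------------------------
# One record per line. A header record opens each client block:
#   {"client_id": "...", "label_names": [...]}
# followed by that client's graph records:
#   {"graph_id": "...", "n": 3, "edges": [[i, j, w], ...],
#    "x": [[...], ...], "y": [0, 1, ...]}
# Edge indices are 0-based, undirected edges stored once, no self-loops.

#' Write a federated dataset to the JSON-lines container
#'
#' @param ds A `fedgat_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_dataset()] for the inverse; the two functions round-trip.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "fedgat_dataset"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (shard in ds$shards) {
    header <- jsonlite::toJSON(
      list(client_id = shard$client_id,
           label_names = ds$label_space$names),
      auto_unbox = TRUE, digits = NA)
    writeLines(header, con)
    for (g in shard$graphs) {
      writeLines(graph_to_json(g), con)
    }
  }
  invisible(path)
}

graph_to_json <- function(g) {
  A <- g$adjacency
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  edges <- if (nrow(idx) == 0L) {
    list()
  } else {
    # 0-based, (i, j, weight), one row per undirected edge
    lapply(seq_len(nrow(idx)), function(r) {
      c(idx[r, 1L] - 1L, idx[r, 2L] - 1L, A[idx[r, 1L], idx[r, 2L]])
    })
  }
  jsonlite::toJSON(
    list(graph_id = g$graph_id, n = nrow(A), edges = edges,
         x = g$node_features, y = g$labels),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
}

#' Read a federated dataset from the JSON-lines container
#'
#' Clients and graphs are kept in file order. Malformed lines and label
#' vectors whose length disagrees with the header's label space raise
#' errors naming the offending line.
#'
#' @param path Path to a file written by [write_dataset()].
#' @return A `fedgat_dataset`.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty dataset file: ", path)
  shards <- list()
  space <- NULL
  cur_id <- NULL
  cur_graphs <- list()
  flush_shard <- function() {
    if (!is.null(cur_id)) {
      shards[[length(shards) + 1L]] <<-
        client_shard(cur_id, cur_graphs, space)
    }
  }
  for (ln in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[ln]], simplifyVector = TRUE),
      error = function(e) {
        stop("parse error at line ", ln, ": ", conditionMessage(e),
             call. = FALSE)
      })
    if (!is.null(rec$client_id)) {
      flush_shard()
      cur_id <- rec$client_id
      cur_graphs <- list()
      new_space <- label_space(rec$label_names)
      if (is.null(space)) {
        space <- new_space
      } else if (!identical(space$names, new_space$names)) {
        stop("label space mismatch at line ", ln, call. = FALSE)
      }
    } else if (!is.null(rec$graph_id)) {
      if (is.null(cur_id)) {
        stop("graph record before any client header at line ", ln,
             call. = FALSE)
      }
      if (length(rec$y) != space$C) {
        stop("schema error at line ", ln, ": label vector length ",
             length(rec$y), " != C = ", space$C, call. = FALSE)
      }
      g <- tryCatch(json_to_graph(rec),
        error = function(e) {
          stop("schema error at line ", ln, ": ", conditionMessage(e),
               call. = FALSE)
        })
      cur_graphs[[length(cur_graphs) + 1L]] <- g
    } else {
      stop("unrecognised record at line ", ln, call. = FALSE)
    }
  }
  flush_shard()
  federated_dataset(shards, space)
}

json_to_graph <- function(rec) {
  n <- as.integer(rec$n)
  A <- matrix(0, n, n)
  edges <- rec$edges
  if (length(edges) > 0L) {
    em <- if (is.matrix(edges)) edges else do.call(rbind, edges)
    for (r in seq_len(nrow(em))) {
      i <- as.integer(em[r, 1L]) + 1L
      j <- as.integer(em[r, 2L]) + 1L
      if (i == j) stop("self-loop on node ", i - 1L)
      if (i < 1L || j < 1L || i > n || j > n) {
        stop("edge index out of range: (", i - 1L, ", ", j - 1L, ")")
      }
      A[i, j] <- em[r, 3L]
      A[j, i] <- em[r, 3L]
    }
  }
  x <- rec$x
  if (!is.matrix(x)) x <- matrix(unlist(x), nrow = n, byrow = TRUE)
  mlgraph(rec$graph_id, A, x, rec$y)
}

# ---- molecular CSV loader -------------------------------------------------

mol_elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "P", "I")

#' Load a molecular CSV (SMILES + binary labels) as a client shard
#'
#' Each parsable SMILES becomes an attributed graph: atoms are nodes,
#' bonds are edges weighted by bond order, and node features are a simple
#' atom descriptor (element one-hot over C/N/O/S/F/Cl/Br/P/I plus "other",
#' and the atom degree). Missing labels are imputed to 0 (absent) and
#' unparsable SMILES rows are skipped; both counts are reported.
#'
#' Requires the ChemmineR package.
#'
#' @param path CSV file with a header row.
#' @param smiles_col Name of the SMILES column.
#' @param label_cols Character vector of label column names (values 0, 1
#'   or empty).
#' @param client_id Identifier for the resulting shard.
#' @param verbose Log imputation/skip counts via `message()`.
#' @return A `fedgat_shard` whose label space is `label_cols`.
#' @export
load_molecular_csv <- function(path, smiles_col, label_cols,
                               client_id = "molecular_csv",
                               verbose = TRUE) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("load_molecular_csv() requires the ChemmineR package")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(smiles_col, label_cols), names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  space <- label_space(label_cols)
  graphs <- list()
  n_skipped <- 0L
  n_imputed <- 0L
  for (r in seq_len(nrow(df))) {
    smi <- df[[smiles_col]][r]
    g <- tryCatch(smiles_to_graph(smi, paste0("row", r)),
                  error = function(e) NULL)
    if (is.null(g)) {
      n_skipped <- n_skipped + 1L
      next
    }
    y <- suppressWarnings(as.numeric(df[r, label_cols]))
    na_count <- sum(is.na(y))
    if (na_count > 0L) {
      n_imputed <- n_imputed + na_count
      y[is.na(y)] <- 0
    }
    graphs[[length(graphs) + 1L]] <- mlgraph(g$graph_id, g$adjacency,
                                             g$node_features, y)
  }
  fg_log("load_molecular_csv: ", length(graphs), " graphs loaded, ",
         n_skipped, " rows skipped (unparsable SMILES), ",
         n_imputed, " missing labels imputed to 0", verbose = verbose)
  if (length(graphs) == 0L) stop("no parsable SMILES rows in ", path)
  shard <- client_shard(client_id, graphs, space)
  attr(shard, "n_skipped") <- n_skipped
  attr(shard, "n_imputed") <- n_imputed
  shard
}

smiles_to_graph <- function(smiles, graph_id) {
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  n <- nrow(ab)
  A <- matrix(0, n, n)
  bb <- ChemmineR::bondblock(sdf)
  if (!is.null(bb) && nrow(bb) > 0L) {
    for (r in seq_len(nrow(bb))) {
      i <- as.integer(bb[r, 1L]); j <- as.integer(bb[r, 2L])
      w <- as.numeric(bb[r, 3L])
      A[i, j] <- w; A[j, i] <- w
    }
  }
  elements <- sub("_[0-9]+$", "", rownames(ab))
  feat <- matrix(0, n, length(mol_elements) + 2L)
  colnames(feat) <- c(mol_elements, "other", "degree")
  for (v in seq_len(n)) {
    k <- match(elements[v], mol_elements)
    if (is.na(k)) k <- length(mol_elements) + 1L
    feat[v, k] <- 1
    feat[v, "degree"] <- sum(A[v, ] > 0)
  }
  list(graph_id = graph_id, adjacency = A, node_features = feat)
}
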