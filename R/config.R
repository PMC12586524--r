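# Run configuration: nested defaults with deep merging. Every tunable the
# simulator exposes lives here, so the CLI, the tests and the acceptance
# script configure runs the same way.

#' Build a run configuration
#'
#' Returns the nested default configuration, deep-merged with any
#' overrides. Blocks:
#'
#' * `labels`: `embedding_provider` ("stub" or a function),
#'   `embedding_dim` (64), `smoothing_eps` (1), `weight_method`
#'   ("ratio"/"exp"), `similarity_threshold` ("mean" or numeric),
#'   `scales` (1:3).
#' * `ae`: label autoencoder — `heads` (4), `hidden_dim` (32),
#'   `mask_rate` (0.15), `epochs` (150), `lr` (5e-3).
#' * `spectral`: `M` retained eigenpairs (8), `N_max` node budget (32),
#'   `epsilon` privacy budget (10), `delta_f` ("auto" or numeric).
#' * `backbone`: `hidden` widths of the first two attention layers
#'   (c(64, 64); the third is C), `heads` per layer (c(4, 4, 1)),
#'   `leaky_slope` (0.2), `head_hidden` classifier-MLP width (64).
#' * `train`: `local_epochs` (10), `lr` (5e-4), `batch_size` (16),
#'   `mode` ("two_stage" or "joint").
#' * `federation`: `rounds` (60), `mode` ("sync"/"async"),
#'   `n_groups` ("auto" or integer), `weighted_fedavg` (FALSE: the
#'   within-group mean is unweighted; TRUE switches to
#'   sample-size weighting matching the global objective), `gating`
#'   ("trace" or "offdiag_mean"), `test_frac` (0.25), `eval_every` (1),
#'   `max_delay` (3: async mode's per-client report delay, in rounds).
#' * `ablate`: `weighted`, `graph`, `multiscale`, `asyagg` switches,
#'   all FALSE.
#'
#' @param ... Named overrides, e.g. `federation = list(rounds = 10)`.
#' @return A nested list of class `fedgat_config`.
#' @export
fedgat_config <- function(...) {
  defaults <- list(
    labels = list(
      embedding_provider = "stub",
      embedding_dim = 64,
      smoothing_eps = 1,
      weight_method = "ratio",
      similarity_threshold = "mean",
      scales = 1:3
    ),
    ae = list(
      heads = 4L,
      hidden_dim = 32L,
      mask_rate = 0.15,
      epochs = 150L,
      lr = 5e-3
    ),
    spectral = list(
      M = 8L,
      N_max = 32L,
      epsilon = 10,
      delta_f = "auto"
    ),
    backbone = list(
      hidden = c(64L, 64L),
      heads = c(4L, 4L, 1L),
      leaky_slope = 0.2,
      head_hidden = 64L
    ),
    train = list(
      local_epochs = 10L,
      lr = 5e-4,
      batch_size = 16L,
      mode = "two_stage"
    ),
    federation = list(
      rounds = 60L,
      mode = "sync",
      n_groups = "auto",
      weighted_fedavg = FALSE,
      gating = "trace",
      test_frac = 0.25,
      eval_every = 1L,
      max_delay = 3L
    ),
    ablate = list(
      weighted = FALSE,
      graph = FALSE,
      multiscale = FALSE,
      asyagg = FALSE
    )
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  structure(deep_merge(defaults, overrides), class = "fedgat_config")
}

deep_merge <- function(base, override) {
  if (length(override) == 0L) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' @export
print.fedgat_config <- function(x, ...) {
  cat("<fedgat_config>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
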