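# broom-style accessors and ggplot2 methods for run histories and
# evaluation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a federated run history
#'
#' One row per (round, metric) pair in long format, ready for plotting.
#'
#' @param x A `fedgat_run`.
#' @param ... Unused.
#' @return A tibble with columns `round`, `metric`, `value`.
#' @export
tidy.fedgat_run <- function(x, ...) {
  x$history |>
    dplyr::select("round", "train_loss", "auc_macro", "cf1", "of1", "map") |>
    tidyr::pivot_longer(-"round", names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
}

#' One-row summary of a federated run
#'
#' @param x A `fedgat_run`.
#' @param ... Unused.
#' @return A tibble with the final evaluation metrics and round count.
#' @export
glance.fedgat_run <- function(x, ...) {
  ev <- x$final_eval
  tibble::tibble(
    rounds = nrow(x$history),
    auc_macro = ev$auc_macro, map = ev$map,
    cp = ev$cp, cr = ev$cr, cf1 = ev$cf1,
    op = ev$op, or_ = ev$or_, of1 = ev$of1
  )
}

#' Tidy an evaluation result
#'
#' @param x A `fedgat_eval`.
#' @param ... Unused.
#' @return A tibble with one row per label and per-label metrics, plus
#'   the macro/micro summary attached as attributes-free summary rows is
#'   avoided: use [glance.fedgat_eval()] for the scalar summary.
#' @export
tidy.fedgat_eval <- function(x, ...) {
  C <- length(x$auc_per_label)
  tibble::tibble(
    label = seq_len(C),
    auc = x$auc_per_label,
    ap = x$ap_per_label,
    precision = x$p_per_label,
    recall = x$r_per_label,
    f1 = x$f1_per_label
  )
}

#' @rdname tidy.fedgat_eval
#' @export
glance.fedgat_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n, auc_macro = x$auc_macro, map = x$map,
    cp = x$cp, cr = x$cr, cf1 = x$cf1,
    op = x$op, or_ = x$or_, of1 = x$of1,
    threshold = x$threshold
  )
}

#' Plot a federated run history
#'
#' Metric trajectories over communication rounds.
#'
#' @param object A `fedgat_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fedgat_run <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "communication round", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-label evaluation metrics
#'
#' @param object A `fedgat_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fedgat_eval <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(-"label", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$label),
                                   y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "label", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
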