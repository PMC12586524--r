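# Multi-label evaluation: per-label ROC-AUC by the midrank statistic with
# macro averaging, per-class (macro) and overall (micro) precision /
# recall / F1, and non-interpolated average precision.

#' Per-label ROC-AUC (midrank statistic) and macro average
#'
#' AUC for each label is the probability that a random positive scores
#' above a random negative, ties counted half (midranks). Labels without
#' both a positive and a negative are excluded from the macro mean (NA in
#' the per-label vector).
#'
#' @param scores n x C score matrix.
#' @param truths n x C binary matrix.
#' @return List with `auc_per_label` (NA for degenerate labels) and
#'   `auc_macro`.
#' @export
roc_auc <- function(scores, truths) {
  scores <- as.matrix(scores); truths <- as.matrix(truths)
  stopifnot(all(dim(scores) == dim(truths)))
  C <- ncol(scores)
  per <- vapply(seq_len(C), function(k) {
    y <- truths[, k]; s <- scores[, k]
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(s, ties.method = "average")
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  if (all(is.na(per))) {
    stop("every label is degenerate (all-positive or all-negative)")
  }
  list(auc_per_label = per, auc_macro = mean(per, na.rm = TRUE))
}

#' Macro (per-class) and micro (overall) precision, recall, F1
#'
#' Scores are thresholded at `threshold`. C-metrics are unweighted means
#' of per-label values, with labels whose denominator is zero
#' contributing 0; O-metrics pool true/false positives and negatives
#' across all label slots, and O-F1 is the harmonic mean of O-P and O-R.
#'
#' @param scores n x C score (or already-binary) matrix.
#' @param truths n x C binary matrix.
#' @param threshold Decision cutoff, default 0.5.
#' @return List with `cp`, `cr`, `cf1`, `op`, `or_`, `of1`, `threshold`,
#'   plus per-label vectors `p_per_label`, `r_per_label`, `f1_per_label`.
#' @export
cfo_metrics <- function(scores, truths, threshold = 0.5) {
  scores <- as.matrix(scores); truths <- as.matrix(truths)
  stopifnot(all(dim(scores) == dim(truths)))
  pred <- (scores >= threshold) * 1
  C <- ncol(pred)
  tp <- colSums(pred * truths)
  fp <- colSums(pred * (1 - truths))
  fn <- colSums((1 - pred) * truths)
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  op <- if (TP + FP > 0) TP / (TP + FP) else 0
  or_ <- if (TP + FN > 0) TP / (TP + FN) else 0
  of1 <- if (op + or_ > 0) 2 * op * or_ / (op + or_) else 0
  list(cp = mean(p), cr = mean(r), cf1 = mean(f1),
       op = op, or_ = or_, of1 = of1, threshold = threshold,
       p_per_label = p, r_per_label = r, f1_per_label = f1)
}

#' Non-interpolated average precision per label and mean AP
#'
#' `AP = (1 / n_pos) * sum over positive ranks of precision-at-rank`,
#' scores sorted descending (ties broken by original order). Degenerate
#' labels (no positives) are NA and excluded from the mean.
#'
#' @param scores n x C score matrix.
#' @param truths n x C binary matrix.
#' @return List with `ap_per_label` and `map`.
#' @export
average_precision <- function(scores, truths) {
  scores <- as.matrix(scores); truths <- as.matrix(truths)
  stopifnot(all(dim(scores) == dim(truths)))
  per <- vapply(seq_len(ncol(scores)), function(k) {
    y <- truths[, k]
    if (sum(y) == 0) return(NA_real_)
    ord <- order(scores[, k], decreasing = TRUE)
    ys <- y[ord]
    hits <- cumsum(ys)
    prec_at <- hits / seq_along(ys)
    sum(prec_at[ys == 1]) / sum(ys)
  }, numeric(1))
  list(ap_per_label = per, map = mean(per, na.rm = TRUE))
}

#' Full multi-label evaluation
#'
#' @param scores n x C matrix of predicted probabilities.
#' @param truths n x C binary matrix.
#' @param threshold Decision cutoff for the P/R/F1 block.
#' @return A `fedgat_eval` object with all metric fields.
#' @export
evaluate_predictions <- function(scores, truths, threshold = 0.5) {
  auc <- roc_auc(scores, truths)
  cfo <- cfo_metrics(scores, truths, threshold)
  ap <- average_precision(scores, truths)
  structure(c(auc, cfo, ap, list(n = nrow(as.matrix(scores)))),
            class = "fedgat_eval")
}

#' @export
print.fedgat_eval <- function(x, ...) {
  cat("<fedgat_eval> n =", x$n, "graphs\n")
  cat(sprintf("  AUC(macro) %.4f  mAP %.4f\n", x$auc_macro, x$map))
  cat(sprintf("  C-P %.4f  C-R %.4f  C-F1 %.4f\n", x$cp, x$cr, x$cf1))
  cat(sprintf("  O-P %.4f  O-R %.4f  O-F1 %.4f  (threshold %.2f)\n",
              x$op, x$or_, x$of1, x$threshold))
  invisible(x)
}
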