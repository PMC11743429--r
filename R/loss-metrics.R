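#' Asymmetric focal-style loss for a single prediction
#'
#' The per-organ binary loss used for imbalanced multi-label training:
#' `-(1 - p)^gamma * log(p)` for unhealthy ground truth (`y = 1`) and
#' `-p^gamma * log(1 - p)` for healthy (`y = 0`). With `gamma = 0` this
#' is exactly binary cross-entropy; `gamma > 0` down-weights easy,
#' well-classified examples so the gradient concentrates on hard ones.
#' Probabilities are clamped to `[epsilon, 1 - epsilon]` before the logs.
#'
#' @param p Predicted probabilities in `[0, 1]` (vectorized).
#' @param y Binary ground-truth labels, same length (0 healthy,
#'   1 unhealthy).
#' @param gamma Focusing exponent, `>= 0`. Default 2.
#' @param epsilon Clamping constant, in `(0, 0.01)`. Default `1e-7`.
#' @return Non-negative loss values, same length as `p`.
#' @examples
#' asl_single(0.5, 1, gamma = 0)  # log(2)
#' asl_single(0.5, 1, gamma = 2)  # 0.25 * log(2)
#' @export
asl_single <- function(p, y, gamma = 2, epsilon = 1e-7) {
  check_asl_args(p, y, gamma, epsilon)
  pc <- clamp(p, epsilon, 1 - epsilon)
  ifelse(y == 1, -(1 - pc)^gamma * log(pc), -pc^gamma * log(1 - pc))
}

check_asl_args <- function(p, y, gamma, epsilon) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must contain probabilities in [0, 1]")
  }
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1")
  if (length(p) != length(y)) abort("`p` and `y` lengths differ")
  if (!is_scalar_number(gamma) || gamma < 0) abort("`gamma` must be >= 0")
  if (!is_scalar_number(epsilon) || epsilon <= 0 || epsilon >= 0.01) {
    abort("`epsilon` must be in (0, 0.01)")
  }
  invisible(TRUE)
}

# d loss / d p at clamped p (used by the trainer; same clamping as the
# forward loss). The gamma * (.)^(gamma - 1) terms vanish at gamma = 0.
asl_grad <- function(p, y, gamma = 2, epsilon = 1e-7) {
  pc <- clamp(p, epsilon, 1 - epsilon)
  g1 <- if (gamma > 0) gamma else 0
  ifelse(y == 1,
         g1 * (1 - pc)^max(gamma - 1, 0) * log(pc) - (1 - pc)^gamma / pc,
         -g1 * pc^max(gamma - 1, 0) * log(1 - pc) + pc^gamma / (1 - pc))
}

#' Batch asymmetric loss over a cohort
#'
#' The training objective: the mean over samples of the summed per-organ
#' asymmetric loss — for an `n` x 5 probability table `P` and label table
#' `Y`, `1/n * sum_j sum_i asl_single(P[j,i], Y[j,i])`.
#'
#' @param probs Numeric matrix (or data frame) of probabilities, samples
#'   in rows, organs in columns.
#' @param labels Binary matrix of the same shape.
#' @inheritParams asl_single
#' @return A single non-negative loss value.
#' @export
asl_batch <- function(probs, labels, gamma = 2, epsilon = 1e-7) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  if (!all(dim(probs) == dim(labels))) {
    abort("`probs` and `labels` must have the same shape")
  }
  if (nrow(probs) < 1L) abort("need at least one sample")
  sum(asl_single(as.vector(probs), as.vector(labels), gamma, epsilon)) /
    nrow(probs)
}

#' Confusion counts for binary predictions
#'
#' Positive means unhealthy (label 1): TP counts correctly identified
#' unhealthy conditions, FP healthy conditions called unhealthy (type I
#' error), FN unhealthy conditions called healthy (type II error), TN
#' correctly identified healthy conditions.
#'
#' @param pred,truth Binary vectors of equal, nonzero length.
#' @return A one-row tibble with integer columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` lengths differ")
  }
  if (length(pred) == 0L) abort("cannot compute confusion counts of zero samples")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    abort("`pred` and `truth` must be binary 0/1")
  }
  tibble(tp = sum(pred == 1 & truth == 1), tn = sum(pred == 0 & truth == 0),
         fp = sum(pred == 1 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

metric_from_counts <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (any(total == 0)) abort("confusion counts sum to zero")
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  tibble(accuracy = (tp + tn) / total, precision = precision,
         recall = recall, f1 = f1,
         zero_denominator = (tp + fp == 0) | (tp + fn == 0))
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, `precision = TP / (TP +
#' FP)`, `recall = TP / (TP + FN)`, and F1 the harmonic mean of precision
#' and recall. A zero denominator in precision or recall yields 0 (a
#' conservative convention, flagged in [metrics_report()]).
#'
#' @param counts A one-row tibble from [confusion_counts()] (or any list
#'   with `tp`, `tn`, `fp`, `fn`).
#' @return A single numeric value.
#' @examples
#' counts <- tibble::tibble(tp = 3, tn = 4, fp = 1, fn = 2)
#' accuracy(counts); precision(counts); recall(counts); f1_score(counts)
#' @export
accuracy <- function(counts) {
  metric_from_counts(counts$tp, counts$tn, counts$fp, counts$fn)$accuracy
}

#' @rdname accuracy
#' @export
precision <- function(counts) {
  metric_from_counts(counts$tp, counts$tn, counts$fp, counts$fn)$precision
}

#' @rdname accuracy
#' @export
recall <- function(counts) {
  metric_from_counts(counts$tp, counts$tn, counts$fp, counts$fn)$recall
}

#' @rdname accuracy
#' @export
f1_score <- function(counts) {
  metric_from_counts(counts$tp, counts$tn, counts$fp, counts$fn)$f1
}

#' Per-organ metrics report
#'
#' Aggregates per-organ confusion counts and metrics from prediction and
#' truth label tables, plus unweighted macro averages over the five
#' organs.
#'
#' @param pred,truth `n` x 5 binary matrices or data frames with columns
#'   in canonical organ order (heart, lung, liver, spleen, kidney).
#' @return A `metrics_report`: tibble with one row per organ (columns
#'   `organ`, `tp`, `tn`, `fp`, `fn`, `accuracy`, `precision`, `recall`,
#'   `f1`, `zero_denominator`) carrying `macro_accuracy` and `macro_f1`
#'   attributes; see [glance.metrics_report()].
#' @export
metrics_report <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)) || ncol(pred) != 5L) {
    abort("`pred` and `truth` must both be n x 5")
  }
  rows <- purrr::map_dfr(seq_len(5L), function(i) {
    cc <- confusion_counts(pred[, i], truth[, i])
    dplyr::bind_cols(tibble(organ = ORGANS[i]), cc,
                     metric_from_counts(cc$tp, cc$tn, cc$fp, cc$fn))
  })
  structure(rows, class = c("metrics_report", class(rows)),
            macro_accuracy = mean(rows$accuracy), macro_f1 = mean(rows$f1))
}

#' Macro-averaged summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A one-row tibble with `macro_accuracy` and `macro_f1` (the
#'   unweighted means over the five organs).
#' @exportS3Method generics::glance
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(macro_accuracy = attr(x, "macro_accuracy"),
         macro_f1 = attr(x, "macro_f1"))
}

#' @exportS3Method generics::tidy
#' @export
tidy.metrics_report <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Write a metrics report to CSV or JSON
#'
#' CSV has one row per organ; JSON additionally carries the macro
#' averages.
#'
#' @param report A `metrics_report`.
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(per_organ = as.data.frame(unclass(report)),
           macro_accuracy = attr(report, "macro_accuracy"),
           macro_f1 = attr(report, "macro_f1")),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(as.data.frame(unclass(report)), path, row.names = FALSE)
  }
  invisible(path)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
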