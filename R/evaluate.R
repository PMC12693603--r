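# Multi-label evaluation metrics. Per-label precision/recall/F1 and the two
# ranking areas are computed from first principles (trapezoidal ROC, step
# PR); aggregates are the unweighted macro means plus Hamming loss and
# subset accuracy.

.confusion <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# F1 with the 0/0 := 0 convention
.f1 <- function(truth, pred) {
  cf <- .confusion(truth, pred)
  p <- if (cf["tp"] + cf["fp"] == 0) 0 else cf["tp"] / (cf["tp"] + cf["fp"])
  r <- if (cf["tp"] + cf["fn"] == 0) 0 else cf["tp"] / (cf["tp"] + cf["fn"])
  if (p + r == 0) return(0)
  unname(2 * p * r / (p + r))
}

#' F1 from precision and recall
#'
#' The harmonic-mean identity `F1 = 2PR / (P + R)` (0 when both are 0),
#' useful for recomputing reported F1 values from printed precision/recall.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return F1 score.
#' @examples
#' f1_from_pr(0.6435, 0.6463)  # 0.6449
#' @export
f1_from_pr <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' ROC-AUC by the trapezoidal rule
#'
#' Area under the ROC curve over the unique score thresholds; equals the
#' normalized Mann-Whitney U statistic (ties counted half).
#'
#' @param truth 0/1 vector.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
roc_auc <- function(truth, scores) {
  pos <- sum(truth == 1); neg <- sum(truth == 0)
  if (pos == 0 || neg == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  t_s <- truth[ord]; s_s <- scores[ord]
  # cumulative TP/FP at each unique threshold
  grp <- cumsum(!duplicated(s_s))
  tp <- cumsum(t_s == 1); fp <- cumsum(t_s == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / pos); fpr <- c(0, fp[last] / neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' PR-AUC by step interpolation (average precision)
#'
#' Average-precision style area under the precision-recall curve: precision
#' is integrated over recall with rectangle (step) interpolation, avoiding
#' the optimistic bias of trapezoidal PR areas.
#'
#' @inheritParams roc_auc
#' @return Area in `[0, 1]`, or `NA` if there are no positives.
#' @export
pr_auc <- function(truth, scores) {
  pos <- sum(truth == 1)
  if (pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  t_s <- truth[ord]; s_s <- scores[ord]
  grp <- cumsum(!duplicated(s_s))
  tp <- cumsum(t_s == 1)
  n_pred <- seq_along(t_s)
  last <- !duplicated(grp, fromLast = TRUE)
  rec <- tp[last] / pos
  prec <- tp[last] / n_pred[last]
  sum(diff(c(0, rec)) * prec)
}

#' Compute per-label and aggregate multi-label metrics
#'
#' @param predictions 0/1 matrix of hard predictions (molecules x labels).
#' @param scores Numeric score matrix in `[0, 1]`, same shape; required only
#'   for the AUC members (pass `NULL` to skip them).
#' @param truth 0/1 ground-truth matrix, same shape.
#' @return An object of class `label_metrics`: list with `per_label` (data
#'   frame: precision, recall, f1, roc_auc, pr_auc, support, positive rate)
#'   and `aggregate` (macro F1 / ROC-AUC / PR-AUC, Hamming loss, subset
#'   accuracy). Labels whose AUC is undefined (no positives or no negatives
#'   in `truth`) are `NA` and excluded from the macro AUC means, with a
#'   warning.
#' @examples
#' truth <- cbind(a = c(1, 0, 1, 0), b = c(0, 0, 1, 1))
#' sc <- cbind(a = c(.9, .2, .8, .1), b = c(.3, .2, .7, .6))
#' compute_metrics((sc >= 0.5) * 1, sc, truth)$aggregate
#' @export
compute_metrics <- function(predictions, scores, truth) {
  predictions <- as.matrix(unclass(predictions))
  truth <- as.matrix(unclass(truth))
  stopifnot(all(dim(predictions) == dim(truth)))
  if (!is.null(scores)) {
    scores <- as.matrix(unclass(scores))
    stopifnot(all(dim(scores) == dim(truth)))
  }
  K <- ncol(truth)
  labels <- colnames(truth) %||% paste0("label_", seq_len(K))
  per <- data.frame(label = labels, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, roc_auc = NA_real_, pr_auc = NA_real_,
                    support = NA_integer_, positive_rate = NA_real_)
  for (k in seq_len(K)) {
    cf <- .confusion(truth[, k], predictions[, k])
    per$precision[k] <- if (cf["tp"] + cf["fp"] == 0) 0 else unname(cf["tp"] / (cf["tp"] + cf["fp"]))
    per$recall[k] <- if (cf["tp"] + cf["fn"] == 0) 0 else unname(cf["tp"] / (cf["tp"] + cf["fn"]))
    per$f1[k] <- .f1(truth[, k], predictions[, k])
    per$support[k] <- sum(truth[, k] == 1)
    per$positive_rate[k] <- mean(truth[, k] == 1)
    if (!is.null(scores)) {
      per$roc_auc[k] <- roc_auc(truth[, k], scores[, k])
      per$pr_auc[k] <- pr_auc(truth[, k], scores[, k])
    }
  }
  if (!is.null(scores) && anyNA(per$roc_auc)) {
    warning("ROC-AUC undefined for degenerate label(s) ",
            paste(labels[is.na(per$roc_auc)], collapse = ", "),
            "; excluded from macro average")
  }
  agg <- list(
    macro_f1 = mean(per$f1),
    macro_roc_auc = if (is.null(scores)) NA_real_ else mean(per$roc_auc, na.rm = TRUE),
    macro_pr_auc = if (is.null(scores)) NA_real_ else mean(per$pr_auc, na.rm = TRUE),
    hamming_loss = mean(predictions != truth),
    subset_accuracy = mean(rowSums(predictions == truth) == K)
  )
  structure(list(per_label = per, aggregate = agg), class = "label_metrics")
}

#' @export
print.label_metrics <- function(x, ...) {
  cat("Multi-label metrics\n")
  print(cbind(x$per_label[, 1, drop = FALSE],
              round(x$per_label[, -1], 4)), row.names = FALSE)
  a <- x$aggregate
  cat(sprintf("macro F1 %.4f | macro ROC-AUC %s | macro PR-AUC %s | Hamming %.4f | subset acc %.4f\n",
              a$macro_f1,
              ifelse(is.na(a$macro_roc_auc), "NA", sprintf("%.4f", a$macro_roc_auc)),
              ifelse(is.na(a$macro_pr_auc), "NA", sprintf("%.4f", a$macro_pr_auc)),
              a$hamming_loss, a$subset_accuracy))
  invisible(x)
}

#' Metrics table shaped like a per-label results report
#'
#' Flattens a `label_metrics` object into a data frame (one row per label)
#' suitable for CSV export.
#'
#' @param metrics A `label_metrics` object.
#' @param model Optional model name column.
#' @return Data frame.
#' @export
metrics_table <- function(metrics, model = NA_character_) {
  cbind(model = model, metrics$per_label)
}
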