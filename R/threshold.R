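# Per-label decision-threshold calibration. Scores from an imbalanced
# multi-label model are rarely well-served by the default 0.5 cutoff; each
# label's threshold is tuned on validation data to maximize that label's F1,
# then applied unchanged at inference.

#' Optimize per-label decision thresholds on validation scores
#'
#' For each label independently, scans a threshold grid and returns the
#' threshold maximizing F1 (prediction = score >= threshold). Ties are broken
#' toward the smallest threshold, which favors recall. Labels without any
#' validation positive get a threshold of 0.5 with a warning.
#'
#' @param scores Score matrix in `[0, 1]` (molecules x labels).
#' @param labels 0/1 label matrix, same shape.
#' @param grid Threshold grid (default `seq(0.01, 0.99, by = 0.01)`).
#' @return An object of class `threshold_vector`: data frame with columns
#'   `label`, `threshold`, `f1` (validation F1 at the chosen threshold),
#'   carrying the grid as an attribute.
#' @examples
#' sc <- cbind(x = c(0.1, 0.2, 0.8, 0.9))
#' y <- cbind(x = c(0, 0, 1, 1))
#' optimize_thresholds(sc, y)  # threshold 0.21: smallest grid point with F1 = 1
#' @export
optimize_thresholds <- function(scores, labels,
                                grid = seq(0.01, 0.99, by = 0.01)) {
  scores <- as.matrix(unclass(scores)); labels <- as.matrix(unclass(labels))
  stopifnot(all(dim(scores) == dim(labels)))
  if (!length(grid)) stop("threshold grid is empty", call. = FALSE)
  grid <- sort(grid)
  K <- ncol(labels)
  lab_names <- colnames(labels) %||% paste0("label_", seq_len(K))
  out <- data.frame(label = lab_names, threshold = NA_real_, f1 = NA_real_)
  for (k in seq_len(K)) {
    y <- labels[, k]; s <- scores[, k]
    if (sum(y == 1) == 0) {
      warning(sprintf("label '%s' has no validation positives; threshold fixed at 0.5",
                      lab_names[k]))
      out$threshold[k] <- 0.5
      out$f1[k] <- .f1(y, as.integer(s >= 0.5))
      next
    }
    f1s <- vapply(grid, function(t) .f1(y, as.integer(s >= t)), numeric(1))
    best <- which.max(f1s)  # first maximum = smallest threshold
    out$threshold[k] <- grid[best]
    out$f1[k] <- f1s[best]
  }
  structure(out, grid = grid, class = c("threshold_vector", "data.frame"))
}

#' Apply calibrated thresholds to a score matrix
#'
#' Predicts label k as 1 iff `score >= threshold_k` (boundary counts as
#' positive).
#'
#' @param scores Score matrix (molecules x labels).
#' @param thresholds A [optimize_thresholds()] result, or a numeric vector of
#'   per-label thresholds.
#' @return Integer 0/1 prediction matrix.
#' @export
apply_thresholds <- function(scores, thresholds) {
  scores <- as.matrix(unclass(scores))
  t_k <- if (inherits(thresholds, "threshold_vector")) thresholds$threshold
         else as.numeric(thresholds)
  if (length(t_k) != ncol(scores)) {
    stop(sprintf("got %d thresholds for %d label columns", length(t_k), ncol(scores)),
         call. = FALSE)
  }
  out <- matrix(0L, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  for (k in seq_len(ncol(scores))) out[, k] <- as.integer(scores[, k] >= t_k[k])
  out
}

#' Before/after gain accounting for threshold calibration
#'
#' Computes absolute gains (after - before) and relative gains
#' (100 * absolute / before, one decimal) for F1 values measured before and
#' after calibration, per model or per label.
#'
#' @param before Named numeric vector of F1 before calibration.
#' @param after Named numeric vector of F1 after calibration, same length.
#' @return An object of class `gain_report`: data frame with columns `name`,
#'   `before_f1`, `after_f1`, `absolute_gain`, `relative_gain_pct` (NA when
#'   `before` is 0).
#' @examples
#' gain_report(c(GAT = 0.1184), c(GAT = 0.5189))  # +0.4005, +338.2%
#' @export
gain_report <- function(before, after) {
  stopifnot(length(before) == length(after))
  nm <- names(before) %||% paste0("item_", seq_along(before))
  absolute <- after - before
  relative <- ifelse(before > 0, round(100 * absolute / before, 1), NA_real_)
  structure(data.frame(name = nm, before_f1 = before, after_f1 = after,
                       absolute_gain = absolute, relative_gain_pct = relative,
                       row.names = NULL),
            class = c("gain_report", "data.frame"))
}
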