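# Applicability-domain assessment. Two complementary views of "is this test
# molecule like the training set": structural similarity (ECFP4 Tanimoto
# against the nearest training molecule, in-domain at >= 0.5) and geometric
# proximity (minimum Euclidean distance in a feature or embedding space,
# in-domain within the 95th percentile of the training set's leave-one-out
# nearest-neighbour distances). The combined call requires both.

#' ECFP4 fingerprints (2048 bits)
#'
#' Circular fingerprints of radius 2 computed by the OpenBabel ECFP4
#' implementation (4096 bits) and folded to 2048 bits by OR-ing the two
#' halves.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Logical matrix (molecules x 2048).
#' @export
ecfp4_fingerprints <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  ids <- sprintf("m%06d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids)))
  fp <- suppressWarnings(ChemmineR::fingerprintOB(sdf, "ECFP4"))
  m <- fp@fpma
  folded <- m[, 1:2048, drop = FALSE] | m[, 2049:4096, drop = FALSE]
  rownames(folded) <- NULL
  folded
}

#' Tanimoto similarity between two fingerprint sets
#'
#' `T(a, b) = |a AND b| / |a OR b|` for every pair (rows of `a` x rows of
#' `b`); two all-zero fingerprints have similarity 0.
#'
#' @param a,b Logical/0-1 fingerprint matrices with equal bit width.
#' @return `nrow(a) x nrow(b)` similarity matrix.
#' @export
tanimoto_matrix <- function(a, b) {
  a <- a * 1; b <- b * 1
  inter <- a %*% t(b)
  ca <- rowSums(a); cb <- rowSums(b)
  uni <- outer(ca, cb, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  out
}

#' Fingerprint-similarity applicability domain
#'
#' Flags each test molecule as in-domain when its maximum ECFP4 Tanimoto
#' similarity to any training molecule reaches the threshold.
#'
#' @param train_smiles,test_smiles SMILES vectors.
#' @param threshold Similarity cutoff (default 0.5).
#' @return Data frame with `max_similarity` and `in_domain` per test
#'   molecule; the training fingerprints are attached as an attribute.
#' @export
tanimoto_ad <- function(train_smiles, test_smiles, threshold = 0.5) {
  if (!length(train_smiles)) stop("empty training set", call. = FALSE)
  fp_train <- ecfp4_fingerprints(train_smiles)
  fp_test <- ecfp4_fingerprints(test_smiles)
  sim <- tanimoto_matrix(fp_test, fp_train)
  max_sim <- apply(sim, 1, max)
  structure(data.frame(max_similarity = max_sim,
                       in_domain = max_sim >= threshold),
            threshold = threshold)
}

#' Distance-based applicability domain
#'
#' In-domain when the minimum Euclidean distance from a test vector to the
#' training vectors does not exceed the 95th percentile (type-7) of the
#' training set's leave-one-out nearest-neighbour distances.
#'
#' @param train_vectors,test_vectors Numeric matrices with equal columns
#'   (processed descriptors for tabular models, pooled graph embeddings for
#'   GNNs).
#' @param percentile Threshold percentile (default 0.95).
#' @return Data frame with `min_distance` and `in_domain` per test row;
#'   attribute `threshold` carries the distance cutoff.
#' @export
distance_ad <- function(train_vectors, test_vectors, percentile = 0.95) {
  train_vectors <- as.matrix(train_vectors)
  test_vectors <- as.matrix(test_vectors)
  if (nrow(train_vectors) < 2) {
    stop("need at least 2 training vectors for leave-one-out distances",
         call. = FALSE)
  }
  stopifnot(ncol(train_vectors) == ncol(test_vectors))
  d_tr <- sqrt(.cross_dist2(train_vectors, train_vectors))
  diag(d_tr) <- Inf
  loo_nn <- apply(d_tr, 1, min)
  thr <- stats::quantile(loo_nn, percentile, type = 7, names = FALSE)
  d_te <- sqrt(.cross_dist2(test_vectors, train_vectors))
  min_d <- apply(d_te, 1, min)
  structure(data.frame(min_distance = min_d, in_domain = min_d <= thr),
            threshold = thr)
}

#' Combine two applicability-domain calls
#'
#' Conservative AND-combination plus the agreement rate between the two
#' methods.
#'
#' @param tanimoto_flags,distance_flags Logical vectors of equal length.
#' @return List with `combined_flags` (both in-domain) and `agreement`
#'   (fraction of samples where the methods agree).
#' @export
combine_ad <- function(tanimoto_flags, distance_flags) {
  if (length(tanimoto_flags) != length(distance_flags)) {
    stop("flag vectors have different lengths", call. = FALSE)
  }
  list(combined_flags = tanimoto_flags & distance_flags,
       agreement = mean(tanimoto_flags == distance_flags))
}

#' Full applicability-domain report
#'
#' Runs both AD methods and the combined judgment, returning the per-sample
#' table and the summary percentages.
#'
#' @inheritParams tanimoto_ad
#' @param train_vectors,test_vectors Feature/embedding matrices for the
#'   distance method.
#' @param threshold Tanimoto cutoff (default 0.5).
#' @return An object of class `ad_report`: list with `per_sample` (max
#'   similarity, min distance, three flags) and `summary` (per-method
#'   in-domain percentages, mean max-similarity, mean min-distance, distance
#'   threshold, agreement percentage).
#' @export
ad_report <- function(train_smiles, test_smiles, train_vectors, test_vectors,
                      threshold = 0.5) {
  tan <- tanimoto_ad(train_smiles, test_smiles, threshold)
  dis <- distance_ad(train_vectors, test_vectors)
  comb <- combine_ad(tan$in_domain, dis$in_domain)
  per_sample <- data.frame(max_similarity = tan$max_similarity,
                           tanimoto_in = tan$in_domain,
                           min_distance = dis$min_distance,
                           distance_in = dis$in_domain,
                           combined_in = comb$combined_flags)
  summary <- list(
    tanimoto_in_pct = 100 * mean(tan$in_domain),
    distance_in_pct = 100 * mean(dis$in_domain),
    combined_in_pct = 100 * mean(comb$combined_flags),
    mean_max_similarity = mean(tan$max_similarity),
    mean_min_distance = mean(dis$min_distance),
    distance_threshold = attr(dis, "threshold"),
    agreement_pct = 100 * comb$agreement
  )
  structure(list(per_sample = per_sample, summary = summary),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Applicability domain (%d test samples)\n", nrow(x$per_sample)))
  cat(sprintf("  Tanimoto : %.2f%% in-domain (mean max similarity %.4f)\n",
              s$tanimoto_in_pct, s$mean_max_similarity))
  cat(sprintf("  Distance : %.2f%% in-domain (mean min distance %.4g, threshold %.4g)\n",
              s$distance_in_pct, s$mean_min_distance, s$distance_threshold))
  cat(sprintf("  Combined : %.2f%% in-domain (agreement %.2f%%)\n",
              s$combined_in_pct, s$agreement_pct))
  invisible(x)
}
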