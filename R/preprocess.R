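# Descriptor-table processing strategies.
#
# Strategy A: tiered missing-value imputation (median / 5-NN / drop), IQR
#             clipping, z-scoring. All parameters are estimated on training
#             rows only and reused for validation/test rows.
# Strategy B: variance filter -> pairwise correlation filter -> per-label
#             mutual-information ranking -> cross-validated RFE with a ridge
#             logistic model.
# Strategy C: PCA or RBF-kernel PCA keeping the smallest number of
#             components reaching 95% cumulative (eigen)variance.

#' Strategy A: impute, clip outliers, standardize
#'
#' Columns with a training missing rate below 5% are median-imputed; between
#' 5% and 30% imputed by 5-nearest-neighbour averaging (Euclidean distance on
#' a median-pre-imputed, internally standardized copy, restricted to columns
#' observed in both rows); above 30% dropped. Surviving columns are clipped
#' to `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 quartiles) and z-scored.
#' Quartiles, means and standard deviations come from training rows only and
#' are applied unchanged to the remaining rows. Columns that end up constant
#' on training rows are dropped with a warning.
#'
#' @param table Numeric matrix or data frame (molecules x descriptors),
#'   `NA` allowed.
#' @param train_idx Row indices used to estimate all parameters (default:
#'   all rows).
#' @param knn_k Neighbours for the moderate-missingness tier (default 5).
#' @return An object of class `strategy_a_fit`: list with `values` (the
#'   transformed table, all rows), `report` (per-column missing rate, method,
#'   clip bounds, mu, sigma), and the frozen transform parameters.
#' @export
preprocess_strategy_a <- function(table, train_idx = NULL, knn_k = 5L) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows", call. = FALSE)
  if (is.null(train_idx)) train_idx <- seq_len(n)
  cols <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  colnames(x) <- cols

  miss_rate <- colMeans(is.na(x[train_idx, , drop = FALSE]))
  method <- ifelse(miss_rate == 0, "none",
                   ifelse(miss_rate < 0.05, "median",
                          ifelse(miss_rate <= 0.30, "knn", "dropped")))
  keep <- method != "dropped"

  # median imputation values (training rows)
  med <- apply(x[train_idx, , drop = FALSE], 2, stats::median, na.rm = TRUE)

  # median-pre-imputed standardized copy for KNN distances
  x_pre <- x
  for (j in seq_len(ncol(x))) x_pre[is.na(x_pre[, j]), j] <- med[j]
  pre_mu <- colMeans(x_pre[train_idx, , drop = FALSE])
  pre_sd <- apply(x_pre[train_idx, , drop = FALSE], 2, stats::sd)
  pre_sd[pre_sd == 0 | is.na(pre_sd)] <- 1
  x_std <- sweep(sweep(x_pre, 2, pre_mu), 2, pre_sd, "/")

  out <- x
  for (j in which(method == "median")) out[is.na(out[, j]), j] <- med[j]
  for (j in which(method == "knn")) {
    need <- which(is.na(x[, j]))
    donors <- train_idx[!is.na(x[train_idx, j])]
    if (!length(donors)) { out[need, j] <- med[j]; next }
    for (i in need) {
      obs_i <- !is.na(x[i, ])
      d <- vapply(donors, function(r) {
        m <- obs_i & !is.na(x[r, ])
        m[j] <- FALSE
        if (!any(m)) return(Inf)
        sqrt(mean((x_std[i, m] - x_std[r, m])^2))
      }, numeric(1))
      nn <- donors[order(d)[seq_len(min(knn_k, length(donors)))]]
      out[i, j] <- mean(x[nn, j])
    }
  }

  # IQR clipping (type-7 quartiles on training rows), then z-scoring.
  # Binary (two-valued) indicator columns are exempt from clipping: for a
  # minority indicator Q1 = Q3, so the IQR rule would flatten the column to
  # a constant, and "outliers" are not meaningful for indicators.
  q1 <- apply(out[train_idx, , drop = FALSE], 2, stats::quantile, 0.25, type = 7, na.rm = TRUE)
  q3 <- apply(out[train_idx, , drop = FALSE], 2, stats::quantile, 0.75, type = 7, na.rm = TRUE)
  lo <- q1 - 1.5 * (q3 - q1)
  hi <- q3 + 1.5 * (q3 - q1)
  binary <- apply(out[train_idx, , drop = FALSE], 2,
                  function(v) length(unique(v[!is.na(v)])) <= 2)
  lo[binary] <- -Inf; hi[binary] <- Inf
  for (j in which(keep)) out[, j] <- pmin(pmax(out[, j], lo[j]), hi[j])
  mu <- colMeans(out[train_idx, , drop = FALSE], na.rm = TRUE)
  sg <- apply(out[train_idx, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  degenerate <- keep & (sg == 0 | is.na(sg))
  if (any(degenerate)) {
    warning("dropping constant column(s) after clipping: ",
            paste(cols[degenerate], collapse = ", "))
    keep <- keep & !degenerate
  }
  for (j in which(keep)) out[, j] <- (out[, j] - mu[j]) / sg[j]

  report <- data.frame(column = cols, missing_rate = miss_rate,
                       method = ifelse(degenerate, "dropped", method),
                       clip_lo = lo, clip_hi = hi, mu = mu, sigma = sg,
                       kept = keep, row.names = NULL)
  structure(list(values = out[, keep, drop = FALSE], report = report,
                 params = list(median = med, pre_mu = pre_mu, pre_sd = pre_sd,
                               clip_lo = lo, clip_hi = hi, mu = mu, sigma = sg,
                               keep = keep, method = method, knn_k = knn_k,
                               train_ref = x[train_idx, , drop = FALSE])),
            class = "strategy_a_fit")
}

#' Apply a fitted Strategy A transform to new rows
#'
#' @param fit A `strategy_a_fit`.
#' @param newtable New rows with the original columns.
#' @return Transformed matrix over the kept columns.
#' @export
strategy_a_transform <- function(fit, newtable) {
  p <- fit$params
  x <- as.matrix(newtable); storage.mode(x) <- "double"
  ref <- p$train_ref
  ref_std <- sweep(sweep(ref, 2, p$median, function(a, b) ifelse(is.na(a), b, a)),
                   2, p$pre_mu)
  ref_std <- sweep(ref_std, 2, p$pre_sd, "/")
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (!any(nas)) next
    if (p$method[j] %in% c("median", "none")) {
      x[nas, j] <- p$median[j]
    } else if (p$method[j] == "knn") {
      donors <- which(!is.na(ref[, j]))
      x_std_row <- function(i) (ifelse(is.na(x[i, ]), p$median, x[i, ]) - p$pre_mu) / p$pre_sd
      for (i in which(nas)) {
        xi <- x_std_row(i); obs_i <- !is.na(x[i, ])
        d <- vapply(donors, function(r) {
          m <- obs_i & !is.na(ref[r, ]); m[j] <- FALSE
          if (!any(m)) return(Inf)
          sqrt(mean((xi[m] - ref_std[r, m])^2))
        }, numeric(1))
        nn <- donors[order(d)[seq_len(min(p$knn_k, length(donors)))]]
        x[i, j] <- mean(ref[nn, j])
      }
    }
  }
  for (j in which(p$keep)) {
    x[, j] <- (pmin(pmax(x[, j], p$clip_lo[j]), p$clip_hi[j]) - p$mu[j]) / p$sigma[j]
  }
  x[, p$keep, drop = FALSE]
}

# Ross (2014) k-nearest-neighbour mutual information estimator for a
# continuous feature against a discrete (binary) target.
.mi_knn <- function(x, y, k = 3L) {
  n <- length(x)
  classes <- unique(y)
  if (length(classes) < 2) return(0)
  # jitter breaks ties deterministically (scaled far below data resolution)
  x <- x + seq_len(n) * 1e-10 * max(1e-12, stats::sd(x))
  m_i <- integer(n); n_y <- integer(n)
  ord_all <- order(x); rank_all <- order(ord_all)
  xs <- x[ord_all]
  for (cl in classes) {
    idx <- which(y == cl)
    nc <- length(idx)
    n_y[idx] <- nc
    kk <- min(k, nc - 1)
    if (kk < 1) { m_i[idx] <- 1L; next }
    xc <- sort(x[idx])
    pos <- findInterval(x[idx], xc)
    for (t in seq_along(idx)) {
      i <- idx[t]
      # distance to kk-th same-class neighbour
      lo <- pos[t]; hi <- pos[t]
      dist_k <- 0
      left <- lo - 1L; right <- hi + 1L
      cnt <- 0L
      while (cnt < kk) {
        dl <- if (left >= 1) abs(x[i] - xc[left]) else Inf
        dr <- if (right <= nc) abs(x[i] - xc[right]) else Inf
        if (dl <= dr) { dist_k <- dl; left <- left - 1L } else { dist_k <- dr; right <- right + 1L }
        cnt <- cnt + 1L
      }
      # neighbours within dist_k in the full sample (strictly inside)
      lo_all <- findInterval(x[i] - dist_k, xs, left.open = TRUE)
      hi_all <- findInterval(x[i] + dist_k, xs, left.open = FALSE)
      cnt_all <- hi_all - lo_all - 1L  # exclude the point itself
      m_i[i] <- max(cnt_all, kk)
    }
  }
  mi <- digamma(n) + digamma(min(k, max(table(y)) - 1)) -
    mean(digamma(n_y)) - mean(digamma(m_i))
  max(0, mi)
}

#' Strategy B: four-stage per-label feature selection
#'
#' On a preprocessed table: (1) remove columns with training variance below
#' `variance_tau`; (2) remove the later column of every pair with
#' `|Pearson rho| > cor_limit` (left-to-right scan, deterministic);
#' (3) per label, rank the survivors by k-NN mutual information with the
#' binary target and keep the top `mi_cap`; (4) recursive feature
#' elimination with an L2-regularized logistic model, choosing the subset
#' size over `rfe_sizes` by cross-validated F1.
#'
#' @param table Preprocessed numeric matrix (Strategy A output).
#' @param labels 0/1 label matrix, rows aligned with `table`.
#' @param train_idx Rows used for selection (default all).
#' @param variance_tau Variance threshold (default 0.01).
#' @param cor_limit Absolute correlation threshold (default 0.95).
#' @param mi_cap Candidates kept after MI ranking (default 64).
#' @param rfe_sizes Candidate subset sizes (default `c(12, 16, 20, 24, 28, 33)`).
#' @param folds Cross-validation folds for RFE (default 5).
#' @param seed Seed for fold assignment.
#' @return An object of class `strategy_b_selection`: named list per label
#'   with `selected` (column names), plus a `trace` describing each stage.
#'   Labels with a single class in training rows are skipped with a warning.
#' @export
select_features_strategy_b <- function(table, labels, train_idx = NULL,
                                       variance_tau = 0.01, cor_limit = 0.95,
                                       mi_cap = 64L,
                                       rfe_sizes = c(12L, 16L, 20L, 24L, 28L, 33L),
                                       folds = 5L, seed = 1L) {
  x <- as.matrix(table)
  y <- as.matrix(unclass(labels))
  stopifnot(nrow(x) == nrow(y))
  if (is.null(train_idx)) train_idx <- seq_len(nrow(x))
  xt <- x[train_idx, , drop = FALSE]

  v <- apply(xt, 2, stats::var)
  after_var <- colnames(x)[!is.na(v) & v >= variance_tau]

  # correlation filter, left-to-right
  xv <- xt[, after_var, drop = FALSE]
  keep <- rep(TRUE, ncol(xv))
  if (ncol(xv) > 1) {
    cm <- suppressWarnings(stats::cor(xv))
    cm[is.na(cm)] <- 0
    for (j in 2:ncol(xv)) {
      if (any(abs(cm[seq_len(j - 1), j]) > cor_limit & keep[seq_len(j - 1)])) {
        keep[j] <- FALSE
      }
    }
  }
  after_cor <- after_var[keep]

  out <- list()
  trace <- list(n_input = ncol(x), after_variance = after_var,
                after_correlation = after_cor)
  for (k in seq_len(ncol(y))) {
    lab <- colnames(y)[k] %||% paste0("label_", k)
    yk <- y[train_idx, k]
    if (length(unique(yk)) < 2) {
      warning(sprintf("label '%s' has a single class in training rows; selection skipped", lab))
      out[[lab]] <- list(selected = character(0), skipped = TRUE)
      next
    }
    mi <- vapply(after_cor, function(cn) .mi_knn(xt[, cn], yk), numeric(1))
    cand <- after_cor[order(mi, decreasing = TRUE)][seq_len(min(mi_cap, length(after_cor)))]
    rfe <- .rfe_logistic(xt[, cand, drop = FALSE], yk,
                         sizes = rfe_sizes[rfe_sizes <= length(cand)],
                         folds = folds, seed = seed + k)
    out[[lab]] <- list(selected = rfe$selected, skipped = FALSE,
                       mi = mi[cand], rfe_cv_f1 = rfe$cv_f1)
  }
  structure(list(per_label = out, trace = trace), class = "strategy_b_selection")
}

# RFE with ridge logistic regression: eliminate by |coefficient| down a path,
# score candidate sizes by stratified-CV F1.
.rfe_logistic <- function(x, y, sizes, folds = 5L, seed = 1L) {
  if (!length(sizes)) sizes <- ncol(x)
  sizes <- sort(unique(pmin(sizes, ncol(x))), decreasing = TRUE)
  .local_rng(seed)
  fold_id <- .stratified_folds(y, folds)
  # lambda large enough to keep the ridge solution well-defined under
  # perfect separation (a vanishing penalty lets coefficients diverge and
  # the returned solution is meaningless)
  fit_rank <- function(cols) {
    f <- glmnet::glmnet(x[, cols, drop = FALSE], y, family = "binomial",
                        alpha = 0, lambda = 0.1, standardize = FALSE)
    abs(as.numeric(f$beta))
  }
  # elimination path from full set down to the smallest size
  path <- list()
  cur <- colnames(x)
  for (s in sizes) {
    while (length(cur) > s) {
      r <- fit_rank(cur)
      drop_n <- max(1L, min(length(cur) - s, ceiling(0.1 * length(cur))))
      cur <- cur[order(r, decreasing = TRUE)][seq_len(length(cur) - drop_n)]
    }
    path[[as.character(s)]] <- cur
  }
  cv_f1 <- vapply(sizes, function(s) {
    cols <- path[[as.character(s)]]
    f1s <- vapply(seq_len(max(fold_id)), function(fd) {
      tr <- fold_id != fd; te <- !tr
      if (length(unique(y[tr])) < 2) return(NA_real_)
      f <- glmnet::glmnet(x[tr, cols, drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = 0.1, standardize = FALSE)
      p <- as.numeric(stats::predict(f, x[te, cols, drop = FALSE], type = "response"))
      .f1(y[te], as.integer(p >= 0.5))
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }, numeric(1))
  best <- sizes[which.max(cv_f1)]
  list(selected = path[[as.character(best)]],
       cv_f1 = stats::setNames(cv_f1, sizes))
}

.stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  id
}

#' Strategy C: PCA / kernel-PCA dimensionality reduction
#'
#' Linear PCA keeps the smallest number of components whose cumulative
#' explained variance reaches `variance_ratio`; kernel PCA (RBF kernel,
#' bandwidth from the median-distance heuristic on training rows) keeps
#' components by the same cumulative-eigenvalue rule. Projections are fitted
#' on training rows only and applied to all rows.
#'
#' @param table Preprocessed numeric matrix.
#' @param method `"pca"` or `"kpca"`.
#' @param train_idx Rows used to fit the projection (default all).
#' @param variance_ratio Cumulative variance to retain (default 0.95).
#' @return List with `values` (all rows x components), `n_components`,
#'   `explained_ratio` and the fitted projection.
#' @export
reduce_strategy_c <- function(table, method = c("pca", "kpca"),
                              train_idx = NULL, variance_ratio = 0.95) {
  method <- match.arg(method)
  x <- as.matrix(table)
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(x))
  xt <- x[train_idx, , drop = FALSE]
  if (method == "pca") {
    pc <- stats::prcomp(xt, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    ratio <- cumsum(ev) / sum(ev)
    m <- which(ratio >= variance_ratio)[1]
    proj <- scale(x, center = pc$center, scale = FALSE) %*% pc$rotation[, seq_len(m), drop = FALSE]
    list(values = proj, n_components = m, explained_ratio = ratio[m],
         fit = list(method = "pca", rotation = pc$rotation[, seq_len(m), drop = FALSE],
                    center = pc$center))
  } else {
    # RBF kernel PCA with explicit eigendecomposition of the doubly centered
    # kernel matrix (all eigenvalues are needed for the cumulative rule)
    d2 <- as.matrix(stats::dist(xt))^2
    sigma2 <- stats::median(d2[upper.tri(d2)])
    if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
    kfun <- function(a, b) exp(-as.matrix(.cross_dist2(a, b)) / (2 * sigma2))
    K <- kfun(xt, xt)
    nt <- nrow(xt)
    H <- diag(nt) - matrix(1 / nt, nt, nt)
    Kc <- H %*% K %*% H
    eg <- eigen(Kc, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    ratio <- cumsum(ev) / sum(ev)
    m <- which(ratio >= variance_ratio)[1]
    alpha <- eg$vectors[, seq_len(m), drop = FALSE]
    alpha <- sweep(alpha, 2, sqrt(pmax(ev[seq_len(m)], 1e-12)), "/")
    Kx <- kfun(x, xt)
    ones_n <- matrix(1 / nt, nrow(x), nt)
    Kx_c <- Kx - ones_n %*% K - Kx %*% matrix(1 / nt, nt, nt) +
      ones_n %*% K %*% matrix(1 / nt, nt, nt)
    proj <- Kx_c %*% alpha
    colnames(proj) <- paste0("KPC", seq_len(m))
    list(values = proj, n_components = m, explained_ratio = ratio[m],
         fit = list(method = "kpca", sigma2 = sigma2, train = xt, alpha = alpha))
  }
}

# squared Euclidean cross-distance matrix
.cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  pmax(outer(an, bn, "+") - 2 * a %*% t(b), 0)
}
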