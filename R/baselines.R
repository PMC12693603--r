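# Descriptor-based base learners, one binary classifier per label
# (binary-relevance decomposition). Model fitting is delegated to the
# established implementations (ranger, e1071, xgboost, nnet); this module
# provides the per-label grid-search CV, probability contracts and score
# assembly around them. The three boosting kinds are distinct xgboost
# configurations: `gbdt` is classic depth-wise boosting with a slow learning
# rate, `xgboost` the default regularized setup, and `lightgbm` a leaf-wise
# histogram configuration (grow_policy = "lossguide").

#' Baseline learner specification
#'
#' @param model_kind One of `"rf"`, `"svm_rbf"`, `"gbdt"`, `"mlp"`,
#'   `"xgboost"`, `"lightgbm"`.
#' @param grid Optional data frame of hyperparameter combinations to search
#'   (defaults per kind; kept small deliberately).
#' @param cv_folds Stratified CV folds for the grid search (default 5).
#' @param seed Integer seed.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(model_kind = c("rf", "svm_rbf", "gbdt", "mlp",
                                         "xgboost", "lightgbm"),
                          grid = NULL, cv_folds = 5L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (is.null(grid)) grid <- .default_grid(model_kind)
  stopifnot(nrow(grid) >= 1, cv_folds >= 2)
  structure(list(model_kind = model_kind, grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 scoring = "f1"),
            class = "baseline_spec")
}

.default_grid <- function(kind) {
  switch(kind,
    rf = expand.grid(num_trees = 300, min_node_size = c(1, 5)),
    svm_rbf = expand.grid(cost = c(1, 10), gamma_scale = 1),
    gbdt = expand.grid(nrounds = c(150, 300), max_depth = 3, eta = 0.05),
    mlp = expand.grid(size = c(8, 16), decay = c(1e-3, 1e-2)),
    xgboost = expand.grid(nrounds = 150, max_depth = c(4, 6), eta = 0.1),
    lightgbm = expand.grid(nrounds = 200, max_leaves = c(15, 31), eta = 0.1)
  )
}

# fit one binary scorer; returns list(fit, predict(newx) -> prob)
.fit_one <- function(kind, x, y, pars, seed) {
  .local_rng(seed)
  if (kind == "rf") {
    fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                          num.trees = pars$num_trees,
                          min.node.size = pars$min_node_size,
                          probability = TRUE, seed = seed, num.threads = 1)
    list(fit = fit,
         predict = function(nx) ranger::predictions(stats::predict(fit, nx, num.threads = 1))[, "1"])
  } else if (kind == "svm_rbf") {
    fit <- e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                      kernel = "radial", cost = pars$cost,
                      gamma = pars$gamma_scale / ncol(x),
                      probability = TRUE, scale = FALSE)
    list(fit = fit,
         predict = function(nx) {
           attr(stats::predict(fit, nx, probability = TRUE), "probabilities")[, "1"]
         })
  } else if (kind == "mlp") {
    fit <- nnet::nnet(x = x, y = y, size = pars$size, decay = pars$decay,
                      maxit = 300, entropy = TRUE, trace = FALSE, MaxNWts = 50000)
    list(fit = fit, predict = function(nx) as.numeric(stats::predict(fit, nx)))
  } else {
    params <- switch(kind,
      gbdt = list(objective = "binary:logistic", max_depth = pars$max_depth,
                  eta = pars$eta, subsample = 0.8, colsample_bytree = 0.8,
                  tree_method = "exact", nthread = 1, seed = seed),
      xgboost = list(objective = "binary:logistic", max_depth = pars$max_depth,
                     eta = pars$eta, lambda = 1, tree_method = "exact",
                     nthread = 1, seed = seed),
      lightgbm = list(objective = "binary:logistic", eta = pars$eta,
                      tree_method = "hist", grow_policy = "lossguide",
                      max_leaves = pars$max_leaves, max_depth = 0,
                      nthread = 1, seed = seed))
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = pars$nrounds, verbose = 0)
    list(fit = fit,
         predict = function(nx) stats::predict(fit, xgboost::xgb.DMatrix(nx)))
  }
}

#' Train per-label baseline classifiers
#'
#' Binary-relevance training of one classifier per label with grid-search
#' hyperparameter selection by stratified cross-validated F1 (threshold 0.5)
#' on the training rows, then a final refit on all training rows. Labels that
#' are single-class on the training rows are skipped with a warning and
#' scored at the training prior.
#'
#' @param x Numeric feature matrix (all rows).
#' @param labels 0/1 label matrix, row-aligned with `x`.
#' @param spec A [baseline_spec()].
#' @param train_idx Training row indices.
#' @param features Optional per-label feature subsets (e.g. from
#'   [select_features_strategy_b()]): named list of column-name vectors.
#' @return An object of class `baseline_model`: per-label fits, chosen
#'   hyperparameters, and `scores` -- a full score matrix in `[0, 1]` for all
#'   rows (training rows included).
#' @export
train_baselines <- function(x, labels, spec, train_idx, features = NULL) {
  stopifnot(inherits(spec, "baseline_spec"))
  x <- as.matrix(x)
  y <- as.matrix(unclass(labels))
  stopifnot(nrow(x) == nrow(y))
  K <- ncol(y)
  lab_names <- colnames(y) %||% paste0("label_", seq_len(K))
  scores <- matrix(NA_real_, nrow(x), K, dimnames = list(rownames(x), lab_names))
  fits <- vector("list", K); names(fits) <- lab_names
  chosen <- vector("list", K); names(chosen) <- lab_names

  for (k in seq_len(K)) {
    cols <- if (!is.null(features)) intersect(features[[lab_names[k]]], colnames(x))
            else colnames(x)
    if (!length(cols)) cols <- colnames(x)
    xk <- x[, cols, drop = FALSE]
    yk <- y[train_idx, k]
    if (length(unique(yk)) < 2) {
      warning(sprintf("label '%s' is single-class on training rows; scored at the prior", lab_names[k]))
      scores[, k] <- mean(yk)
      next
    }
    seed_k <- spec$seed + 97L * k
    # grid search by stratified-CV F1
    best_pars <- spec$grid[1, , drop = FALSE]
    if (nrow(spec$grid) > 1) {
      .local_rng(seed_k)
      fold_id <- .stratified_folds(yk, spec$cv_folds)
      cv_f1 <- vapply(seq_len(nrow(spec$grid)), function(g) {
        pars <- spec$grid[g, , drop = FALSE]
        mean(vapply(seq_len(spec$cv_folds), function(fd) {
          tr <- which(fold_id != fd); te <- which(fold_id == fd)
          if (length(unique(yk[tr])) < 2) return(NA_real_)
          m <- .fit_one(spec$model_kind, xk[train_idx[tr], , drop = FALSE],
                        yk[tr], pars, seed_k + fd)
          .f1(yk[te], as.integer(m$predict(xk[train_idx[te], , drop = FALSE]) >= 0.5))
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      best_pars <- spec$grid[which.max(cv_f1), , drop = FALSE]
      chosen[[k]] <- list(pars = best_pars, cv_f1 = cv_f1)
    }
    m <- .fit_one(spec$model_kind, xk[train_idx, , drop = FALSE], yk,
                  best_pars, seed_k)
    fits[[k]] <- list(model = m, cols = cols, pars = best_pars)
    scores[, k] <- pmin(pmax(m$predict(xk), 0), 1)
  }
  structure(list(model_kind = spec$model_kind, fits = fits, chosen = chosen,
                 scores = scores, train_idx = train_idx),
            class = "baseline_model")
}

#' Score new rows with a trained baseline model
#'
#' @param object A `baseline_model`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Score matrix in `[0, 1]`.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  K <- length(object$fits)
  out <- matrix(NA_real_, nrow(newdata), K,
                dimnames = list(rownames(newdata), names(object$fits)))
  for (k in seq_len(K)) {
    f <- object$fits[[k]]
    if (is.null(f)) { out[, k] <- mean(object$scores[object$train_idx, k]); next }
    out[, k] <- pmin(pmax(f$model$predict(newdata[, f$cols, drop = FALSE]), 0), 1)
  }
  out
}

#' Label-prior reference scorer
#'
#' The no-information baseline: every molecule receives each label's training
#' positive rate as its score. Used as the floor that trained models must
#' beat.
#'
#' @param labels 0/1 label matrix.
#' @param train_idx Rows defining the prior.
#' @param n_rows Number of rows to score (default all rows of `labels`).
#' @return Score matrix.
#' @export
prior_scores <- function(labels, train_idx, n_rows = nrow(labels)) {
  y <- as.matrix(unclass(labels))
  pri <- colMeans(y[train_idx, , drop = FALSE])
  matrix(pri, n_rows, ncol(y), byrow = TRUE, dimnames = list(NULL, colnames(y)))
}
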