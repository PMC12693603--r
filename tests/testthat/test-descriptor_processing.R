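# Strategies A (impute/clip/standardize), B (four-stage selection) and
# C (PCA / kernel PCA).

test_that("IQR clipping reproduces the hand-computed type-7 bounds", {
  x <- cbind(a = c(1, 2, 3, 4, 100), b = c(10, 20, 30, 40, 50))
  fit <- preprocess_strategy_a(x)
  rep_a <- fit$report[fit$report$column == "a", ]
  expect_equal(rep_a$clip_lo, 2 - 1.5 * 2)   # Q1=2, Q3=4, IQR=2
  expect_equal(rep_a$clip_hi, 4 + 1.5 * 2)
  # undo the z-score to recover the clipped values
  raw <- fit$values[, "a"] * rep_a$sigma + rep_a$mu
  expect_equal(unname(raw), c(1, 2, 3, 4, 7))
})

test_that("missingness tiers route to median, knn, or removal", {
  set.seed(1)
  n <- 60
  x <- cbind(low = rnorm(n), mid = rnorm(n), high = rnorm(n), clean = rnorm(n))
  x[1:2, "low"] <- NA          # ~3% -> median
  x[1:12, "mid"] <- NA         # 20% -> knn
  x[1:25, "high"] <- NA        # ~42% -> dropped
  fit <- preprocess_strategy_a(x)
  rp <- stats::setNames(fit$report$method, fit$report$column)
  expect_equal(unname(rp["low"]), "median")
  expect_equal(unname(rp["mid"]), "knn")
  expect_equal(unname(rp["high"]), "dropped")
  expect_false("high" %in% colnames(fit$values))
  expect_false(anyNA(fit$values))
  # every input column accounted for exactly once
  expect_setequal(fit$report$column, colnames(x))
})

test_that("surviving columns are standardized on training rows and the
           transform is idempotent", {
  set.seed(2)
  x <- matrix(rexp(200 * 8, rate = 0.1), 200, 8)
  x[sample(length(x), 50)] <- NA
  tr <- 1:140
  fit <- preprocess_strategy_a(x, train_idx = tr)
  for (j in seq_len(ncol(fit$values))) {
    expect_lt(abs(mean(fit$values[tr, j])), 1e-9)
    expect_lt(abs(stats::sd(fit$values[tr, j]) - 1), 1e-9)
  }
  again <- preprocess_strategy_a(fit$values, train_idx = tr)
  expect_lt(max(abs(again$values - fit$values)), 1e-9)
})

test_that("transform parameters never depend on non-training rows", {
  set.seed(3)
  x <- matrix(rnorm(100 * 5), 100, 5)
  x[sample(length(x), 30)] <- NA
  tr <- 1:64
  f1 <- preprocess_strategy_a(x, train_idx = tr)
  x2 <- x
  x2[65:100, ] <- x2[65:100, ] * 50 + 7   # mutate held-out rows only
  f2 <- preprocess_strategy_a(x2, train_idx = tr)
  expect_equal(f1$report, f2$report)
  expect_equal(f1$values[tr, ], f2$values[tr, ])
})

test_that("strategy B stages: variance, duplicate-correlation, planted signal", {
  set.seed(4)
  n <- 160
  base <- matrix(rnorm(n * 10), n, 10)
  x <- cbind(base,
             const = rep(5, n),                 # variance stage
             dup = base[, 1] + rnorm(n, sd = 1e-4),  # correlation stage
             planted = rep(c(0, 1), length.out = n))
  colnames(x)[1:10] <- sprintf("n%02d", 1:10)
  y <- cbind(lab = x[, "planted"])
  sel <- select_features_strategy_b(x, y, variance_tau = 0.01,
                                    rfe_sizes = c(3, 6), mi_cap = 8)
  expect_false("const" %in% sel$trace$after_variance)
  expect_false("dup" %in% sel$trace$after_correlation)
  expect_true("n01" %in% sel$trace$after_correlation)  # earlier copy survives
  expect_true("planted" %in% sel$per_label$lab$selected)
  expect_lte(length(sel$per_label$lab$selected), 8)
})

test_that("strategy B skips single-class labels with a warning", {
  x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- cbind(dead = rep(0L, 50))
  expect_warning(sel <- select_features_strategy_b(x, y), "single class")
  expect_length(sel$per_label$dead$selected, 0)
})

test_that("mutual information ranks signal above noise and vanishes under
           permutation", {
  set.seed(5)
  y <- rep(0:1, each = 120)
  signal <- rnorm(240) + 1.5 * y
  noise <- rnorm(240)
  mi_s <- odorgraph:::.mi_knn(signal, y)
  mi_n <- odorgraph:::.mi_knn(noise, y)
  expect_gt(mi_s, mi_n + 0.1)
  mi_p <- odorgraph:::.mi_knn(signal[sample(240)], y)
  expect_lt(mi_p, 0.05)
})

test_that("PCA keeps the smallest component count reaching 95% variance", {
  set.seed(6)
  rank2 <- matrix(rnorm(600 * 2), 600, 2) %*% matrix(rnorm(2 * 10), 2, 10)
  expect_equal(reduce_strategy_c(rank2, "pca")$n_components, 2)
  iso <- matrix(rnorm(10000 * 5), 10000, 5)
  expect_equal(reduce_strategy_c(iso, "pca")$n_components, 5)
  red <- reduce_strategy_c(matrix(rnorm(300 * 12), 300, 12), "pca")
  expect_gte(red$explained_ratio, 0.95)
})

test_that("kernel PCA follows the cumulative-eigenvalue rule and is fitted on
           training rows only", {
  set.seed(7)
  x <- matrix(rnorm(150 * 6), 150, 6)
  tr <- 1:100
  r1 <- reduce_strategy_c(x, "kpca", train_idx = tr)
  expect_gte(r1$explained_ratio, 0.95)
  expect_equal(nrow(r1$values), 150)
  x2 <- x; x2[101:150, ] <- x2[101:150, ] + 100
  r2 <- reduce_strategy_c(x2, "kpca", train_idx = tr)
  expect_equal(r1$n_components, r2$n_components)
  expect_equal(r1$values[tr, ], r2$values[tr, ])
  expect_error(reduce_strategy_c(x[1, , drop = FALSE], "pca"), "at least 2")
})
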