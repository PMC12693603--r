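# End-to-end orchestration: data loading or synthesis, splitting, model
# training (GNNs and descriptor baselines), post-hoc threshold calibration on
# validation rows only, test evaluation, applicability-domain assessment and
# fragment interpretation, with all reports written to a run directory.
#
# Leakage discipline: split parameters, preprocessing statistics and
# calibrated thresholds are computed from training/validation rows only; the
# orchestrator asserts the index sets are disjoint before any model sees
# them.

#' Train/validation/test split
#'
#' `mode = "random"` shuffles; `mode = "per_label_stratified"` uses greedy
#' iterative stratification: labels are processed from rarest to most
#' frequent and each positive sample goes to the split with the largest
#' remaining demand for that label, subject to split capacities. Falls back
#' to random (with a warning) when any label has fewer than 3 positives.
#'
#' @param labels 0/1 label matrix.
#' @param fractions Train/validation/test fractions summing to 1
#'   (default `c(0.64, 0.16, 0.20)`).
#' @param mode `"per_label_stratified"` (default) or `"random"`.
#' @param seed Integer seed.
#' @return List with integer vectors `train`, `validation`, `test`
#'   (disjoint, exhaustive).
#' @export
make_split <- function(labels, fractions = c(0.64, 0.16, 0.20),
                       mode = c("per_label_stratified", "random"), seed = 1L) {
  mode <- match.arg(mode)
  y <- as.matrix(unclass(labels))
  n <- nrow(y)
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  n_va <- round(fractions[2] * n)
  n_te <- round(fractions[3] * n)
  n_tr <- n - n_va - n_te
  .local_rng(seed)
  if (mode == "per_label_stratified" && any(colSums(y) < 3)) {
    warning("label(s) with fewer than 3 positives; falling back to random split")
    mode <- "random"
  }
  if (mode == "random") {
    ord <- sample(n)
    return(list(train = sort(ord[seq_len(n_tr)]),
                validation = sort(ord[n_tr + seq_len(n_va)]),
                test = sort(ord[n_tr + n_va + seq_len(n_te)])))
  }
  cap <- c(n_tr, n_va, n_te)
  desired <- outer(colSums(y), fractions)   # labels x splits
  assign <- integer(n)                      # 0 = unassigned
  remaining_pos <- colSums(y)
  repeat {
    open <- which(remaining_pos > 0)
    if (!length(open)) break
    k <- open[which.min(remaining_pos[open])]
    idx <- which(assign == 0 & y[, k] == 1)
    idx <- sample(idx)
    for (i in idx) {
      s_ok <- which(cap > 0)
      if (!length(s_ok)) { s <- which.max(cap) } else {
        s <- s_ok[order(-desired[k, s_ok], -cap[s_ok])][1]
      }
      assign[i] <- s
      cap[s] <- cap[s] - 1
      pos_k <- which(y[i, ] == 1)
      desired[pos_k, s] <- desired[pos_k, s] - 1
      remaining_pos[pos_k] <- remaining_pos[pos_k] - 1
    }
  }
  left <- which(assign == 0)
  if (length(left)) {
    left <- sample(left)
    for (i in left) {
      s <- which.max(cap)
      assign[i] <- s
      cap[s] <- cap[s] - 1
    }
  }
  split <- list(train = which(assign == 1), validation = which(assign == 2),
                test = which(assign == 3))
  # per-label stratification quality check
  global <- colMeans(y)
  for (s in split) {
    dev <- abs(colMeans(y[s, , drop = FALSE]) - global)
    if (any(dev > 0.05)) {
      warning(sprintf("stratified split deviates by up to %.1f pp on label '%s'",
                      100 * max(dev), colnames(y)[which.max(dev)]))
    }
  }
  split
}

#' Pipeline run configuration
#'
#' Either point `molecules_csv` (and optionally `descriptors_csv`) at
#' existing files, or set `synthetic` to generate the study data in-run.
#'
#' @param synthetic `NULL`, or a list with `n_molecules` (and optionally
#'   `rule_table`, `grammar`, `descriptor_spec`).
#' @param molecules_csv CSV with a `smiles` column plus one 0/1 column per
#'   label (ignored when `synthetic` is set).
#' @param descriptors_csv Optional row-aligned descriptor CSV.
#' @param models List of model blocks. A GNN block:
#'   `list(name=, type="gnn", architecture=, loss=, ...)` (extra fields are
#'   passed to [gnn_config()]). A baseline block: `list(name=, type="baseline",
#'   model_kind=, strategy=)` with strategy one of `"A"`, `"B"`, `"C_pca"`,
#'   `"C_kpca"`.
#' @param split_fractions,split_mode Passed to [make_split()].
#' @param calibration_grid Threshold grid for [optimize_thresholds()].
#' @param ad,interpret Toggles for the applicability-domain and
#'   interpretability stages.
#' @param seed Master seed for the run.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = list(n_molecules = 600L),
                       molecules_csv = NULL, descriptors_csv = NULL,
                       models = list(list(name = "gcn_focal", type = "gnn",
                                          architecture = "gcn", loss = "focal")),
                       split_fractions = c(0.64, 0.16, 0.20),
                       split_mode = c("per_label_stratified", "random"),
                       calibration_grid = seq(0.01, 0.99, by = 0.01),
                       ad = TRUE, interpret = TRUE,
                       seed = 1L, out_dir = tempfile("odorgraph_run_")) {
  split_mode <- match.arg(split_mode)
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8, length(models) >= 1)
  if (is.null(synthetic) && is.null(molecules_csv)) {
    stop("either synthetic generation or molecules_csv must be given", call. = FALSE)
  }
  structure(list(synthetic = synthetic, molecules_csv = molecules_csv,
                 descriptors_csv = descriptors_csv, models = models,
                 split_fractions = split_fractions, split_mode = split_mode,
                 calibration_grid = calibration_grid, ad = ad,
                 interpret = interpret, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline
#'
#' Generates or loads the data, splits it, trains every configured model,
#' calibrates per-label thresholds on the validation rows, evaluates on the
#' test rows before and after calibration, and (optionally) runs the
#' applicability-domain and fragment-interpretation stages. All reports,
#' the resolved configuration and a log with the seeds used are written to
#' `config$out_dir`; a rerun with an identical configuration reproduces the
#' metrics exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the split, per-model results (metrics,
#'   thresholds, gains, AD report, fragment tables) and the comparison
#'   table. The same content is written to the run directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(msg, "\n"); cat(msg, "\n", file = log_path, append = TRUE)
  }
  logf("run seed %d, output %s", config$seed, config$out_dir)

  # ---- data ----
  needs_desc <- any(vapply(config$models, function(m) m$type == "baseline", logical(1)))
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    gcfg <- generation_config(syn$n_molecules, seed = config$seed,
                              rule_table = syn$rule_table %||% default_rule_table())
    smiles <- generate_molecules(gcfg, grammar = syn$grammar %||% default_grammar())
    labels <- plant_labels(smiles, gcfg)
    logf("generated %d molecules; label frequencies: %s", length(smiles),
         paste(sprintf("%s=%.3f", colnames(labels), attr(labels, "frequencies")),
               collapse = " "))
    descriptors <- NULL
    if (needs_desc) {
      descriptors <- synth_descriptor_table(
        smiles, syn$descriptor_spec %||% descriptor_noise_spec(),
        seed = config$seed)
    }
    write_synthetic_csv(smiles, labels, config$out_dir, descriptors)
  } else {
    tab <- utils::read.csv(config$molecules_csv, check.names = FALSE)
    stopifnot("smiles" %in% names(tab))
    smiles <- tab$smiles
    labels <- as.matrix(tab[, setdiff(names(tab), "smiles"), drop = FALSE])
    descriptors <- if (!is.null(config$descriptors_csv)) {
      as.matrix(utils::read.csv(config$descriptors_csv, check.names = FALSE))
    } else NULL
    if (needs_desc && is.null(descriptors)) {
      stop("baseline models configured but no descriptor table given", call. = FALSE)
    }
  }
  y <- as.matrix(unclass(labels))

  needs_graphs <- any(vapply(config$models, function(m) m$type == "gnn", logical(1)))
  graphs <- if (needs_graphs || config$ad) smiles_to_graphs(smiles) else NULL

  # ---- split ----
  split <- make_split(y, config$split_fractions, config$split_mode,
                      seed = config$seed + 1L)
  stopifnot(!anyDuplicated(c(split$train, split$validation, split$test)))
  logf("split sizes: train %d / validation %d / test %d",
       length(split$train), length(split$validation), length(split$test))

  results <- list()
  comparison <- data.frame()
  for (mi in seq_along(config$models)) {
    mb <- config$models[[mi]]
    name <- mb$name %||% sprintf("model_%d", mi)
    logf("training %s (%s)", name, mb$type)
    if (mb$type == "gnn") {
      extra <- mb[setdiff(names(mb), c("name", "type"))]
      extra$seed <- extra$seed %||% (config$seed + 100L + mi)
      gcfg2 <- do.call(gnn_config, extra)
      model <- train_gnn(graphs, y, gcfg2, split$train, split$validation)
      logf("  best epoch %d, validation macro F1 %.4f", model$best_epoch,
           model$best_val_f1)
      scores_all <- predict(model, graphs)
      vectors_train <- predict(model, graphs[split$train], type = "embeddings")
      vectors_test <- predict(model, graphs[split$test], type = "embeddings")
    } else {
      strat <- mb$strategy %||% "A"
      fitA <- preprocess_strategy_a(descriptors, train_idx = split$train)
      feats <- NULL
      xmat <- fitA$values
      if (strat == "B") {
        selB <- select_features_strategy_b(fitA$values, y,
                                           train_idx = split$train,
                                           seed = config$seed + 200L + mi)
        feats <- lapply(selB$per_label, `[[`, "selected")
      } else if (strat %in% c("C_pca", "C_kpca")) {
        red <- reduce_strategy_c(fitA$values,
                                 if (strat == "C_pca") "pca" else "kpca",
                                 train_idx = split$train)
        xmat <- red$values
        colnames(xmat) <- colnames(xmat) %||% paste0("PC", seq_len(ncol(xmat)))
      }
      bspec <- baseline_spec(mb$model_kind, grid = mb$grid,
                             seed = config$seed + 300L + mi)
      model <- train_baselines(xmat, y, bspec, split$train, features = feats)
      scores_all <- model$scores
      vectors_train <- xmat[split$train, , drop = FALSE]
      vectors_test <- xmat[split$test, , drop = FALSE]
    }

    sc_val <- scores_all[split$validation, , drop = FALSE]
    sc_test <- scores_all[split$test, , drop = FALSE]
    y_val <- y[split$validation, , drop = FALSE]
    y_test <- y[split$test, , drop = FALSE]

    before <- compute_metrics((sc_test >= 0.5) * 1L, sc_test, y_test)
    thr <- optimize_thresholds(sc_val, y_val, grid = config$calibration_grid)
    pred_test <- apply_thresholds(sc_test, thr)
    after <- compute_metrics(pred_test, sc_test, y_test)
    gains <- gain_report(
      stats::setNames(before$per_label$f1, before$per_label$label),
      stats::setNames(after$per_label$f1, after$per_label$label))
    macro_gain <- gain_report(c(macro_f1 = before$aggregate$macro_f1),
                              c(macro_f1 = after$aggregate$macro_f1))
    logf("  test macro F1 %.4f -> %.4f after calibration",
         before$aggregate$macro_f1, after$aggregate$macro_f1)

    adr <- NULL
    if (config$ad) {
      adr <- ad_report(smiles[split$train], smiles[split$test],
                       vectors_train, vectors_test)
      logf("  AD in-domain: tanimoto %.1f%%, distance %.1f%%, combined %.1f%%",
           adr$summary$tanimoto_in_pct, adr$summary$distance_in_pct,
           adr$summary$combined_in_pct)
    }

    fragments <- NULL
    if (config$interpret && mb$type == "gnn") {
      fragments <- lapply(seq_len(ncol(y)), function(k) {
        suppressWarnings(fragment_profile(
          model, graphs[split$test], y_test, pred_test, k))
      })
      names(fragments) <- colnames(y)
    }

    res <- list(name = name, type = mb$type, thresholds = thr,
                metrics_before = before, metrics_after = after,
                gains = gains, macro_gain = macro_gain, ad = adr,
                fragments = fragments, model = model)
    results[[name]] <- res
    comparison <- rbind(comparison, data.frame(
      model = name, type = mb$type,
      macro_f1_before = before$aggregate$macro_f1,
      macro_f1_after = after$aggregate$macro_f1,
      macro_roc_auc = after$aggregate$macro_roc_auc,
      macro_pr_auc = after$aggregate$macro_pr_auc,
      hamming_loss = after$aggregate$hamming_loss,
      subset_accuracy = after$aggregate$subset_accuracy))

    # ---- per-model reports ----
    pfx <- file.path(config$out_dir, name)
    utils::write.csv(metrics_table(after, name), paste0(pfx, "_metrics.csv"),
                     row.names = FALSE)
    .write_json(list(aggregate = after$aggregate,
                     per_label = after$per_label), paste0(pfx, "_metrics.json"))
    .write_json(stats::setNames(
      lapply(seq_len(nrow(thr)), function(i) list(threshold = thr$threshold[i],
                                                  f1_at_threshold = thr$f1[i])),
      thr$label), paste0(pfx, "_thresholds.json"))
    utils::write.csv(as.data.frame(gains), paste0(pfx, "_gains.csv"),
                     row.names = FALSE)
    if (!is.null(adr)) {
      utils::write.csv(adr$per_sample, paste0(pfx, "_ad.csv"), row.names = FALSE)
      .write_json(adr$summary, paste0(pfx, "_ad.json"))
    }
    if (!is.null(fragments)) {
      ft <- do.call(rbind, lapply(names(fragments), function(lb) {
        f <- fragments[[lb]]
        if (!nrow(f)) return(NULL)
        cbind(label = lb, f)
      }))
      if (!is.null(ft)) utils::write.csv(ft, paste0(pfx, "_fragments.csv"),
                                         row.names = FALSE)
    }
    if (mb$type == "gnn") {
      .write_json(model$history, paste0(pfx, "_history.json"))
    }
  }

  utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE)
  .write_json(list(seed = config$seed, split_fractions = config$split_fractions,
                   split_mode = config$split_mode,
                   n_molecules = length(smiles),
                   models = lapply(config$models, function(m) m[setdiff(names(m), "grid")]),
                   r_version = as.character(getRversion())),
              file.path(config$out_dir, "config.json"))
  logf("run complete")
  invisible(list(split = split, results = results, comparison = comparison,
                 smiles = smiles, labels = labels, out_dir = config$out_dir))
}
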