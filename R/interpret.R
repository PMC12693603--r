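# Fragment-level interpretability: node importances from gradients (any
# architecture) or attention (GAT), percentile-thresholded connected
# components, functional-group annotation via the SMARTS library, and
# aggregation over correctly predicted molecules into per-label fragment
# tables.

#' Gradient-based node importance
#'
#' For one molecule and one target label, the importance of atom i is the
#' sum over the 25 input feature slots of the absolute gradient of the
#' pre-sigmoid logit with respect to that atom's features.
#'
#' @param model A `trained_gnn`.
#' @param graph A `molecular_graph`.
#' @param label_index Target label (1-based).
#' @return An object of class `node_importance`: numeric vector (one
#'   non-negative score per atom) with attribute `method = "gradient"`.
#' @export
gradient_node_importance <- function(model, graph, label_index) {
  dX <- .gnn_input_gradient(model, graph, label_index)
  structure(rowSums(abs(dX)), method = "gradient", smiles = graph$smiles,
            class = "node_importance")
}

#' Attention-based node importance (GAT)
#'
#' `I_i = (1/(L*H)) * sum_l sum_h sum_{j in N(i)} alpha_ij^{(l,h)}`: the
#' attention mass node i's neighbours (self-loop excluded) receive in i's
#' aggregation, averaged over layers and heads.
#'
#' @param model A `trained_gnn` with GAT architecture.
#' @param graph A `molecular_graph`.
#' @return A `node_importance` vector with attribute `method = "attention"`.
#' @export
attention_node_importance <- function(model, graph) {
  att <- gnn_attention(model, graph)  # errors for non-GAT
  n <- nrow(graph$node_features)
  L <- length(att)
  H <- max(att[[1]]$head)
  imp <- numeric(n)
  for (l in seq_len(L)) {
    a <- att[[l]]
    nb <- a[a$src != a$dst, , drop = FALSE]   # neighbours only
    if (nrow(nb)) {
      s <- rowsum(nb$alpha, group = nb$dst)
      imp[as.integer(rownames(s))] <- imp[as.integer(rownames(s))] + s[, 1]
    }
  }
  structure(imp / (L * H), method = "attention", smiles = graph$smiles,
            class = "node_importance")
}

#' Extract important fragments from a molecule
#'
#' Selects atoms whose importance reaches the 75th percentile (type-7,
#' ties included) of the molecule's scores, groups them into connected
#' components by BFS over the molecular bonds restricted to selected atoms,
#' and annotates each component with the highest-priority functional group
#' from the SMARTS library whose match overlaps it (else "small fragment").
#'
#' @param graph A `molecular_graph`.
#' @param importance A `node_importance` (or numeric vector) aligned with
#'   the graph's atoms.
#' @param library SMARTS library data frame (default [smarts_library()]).
#' @param percentile Selection percentile (default 0.75).
#' @return Data frame of fragment records: `fragment` (group name),
#'   `n_atoms`, `mean_importance`, and `atoms` (list column of atom index
#'   vectors; each set is connected and disjoint from the others).
#' @export
extract_fragments <- function(graph, importance, library = smarts_library(),
                              percentile = 0.75) {
  n <- nrow(graph$node_features)
  if (n == 0) stop("empty graph", call. = FALSE)
  imp <- as.numeric(importance)
  stopifnot(length(imp) == n)
  thr <- stats::quantile(imp, percentile, type = 7, names = FALSE)
  sel <- which(imp >= thr)
  if (!length(sel)) return(.empty_fragments())
  # adjacency restricted to selected nodes
  ei <- graph$edge_index
  adj <- vector("list", n)
  if (nrow(ei)) {
    for (r in seq_len(nrow(ei))) {
      s <- ei[r, 1]; d <- ei[r, 2]
      if (s %in% sel && d %in% sel) adj[[s]] <- c(adj[[s]], d)
    }
  }
  # BFS components
  comps <- list()
  seen <- logical(n)
  for (v in sel) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  # annotate with the SMARTS library (priority order, first overlap wins)
  lib <- library[order(library$priority), , drop = FALSE]
  mol <- .as_mol(graph$smiles)
  match_atoms <- lapply(lib$smarts, function(s) {
    m <- smarts_match(s, mol)
    if (length(m)) unique(unlist(m)) else integer(0)
  })
  rec <- lapply(comps, function(cp) {
    grp <- "small fragment"
    for (i in seq_len(nrow(lib))) {
      if (length(intersect(cp, match_atoms[[i]]))) { grp <- lib$name[i]; break }
    }
    list(fragment = grp, n_atoms = length(cp), mean_importance = mean(imp[cp]),
         atoms = cp)
  })
  data.frame(fragment = vapply(rec, `[[`, character(1), "fragment"),
             n_atoms = vapply(rec, `[[`, integer(1), "n_atoms"),
             mean_importance = vapply(rec, `[[`, numeric(1), "mean_importance"),
             atoms = I(lapply(rec, `[[`, "atoms")))
}

.empty_fragments <- function() {
  data.frame(fragment = character(0), n_atoms = integer(0),
             mean_importance = numeric(0), atoms = I(list()))
}

#' Aggregate fragment records across molecules
#'
#' Pools per-molecule fragment records into a ranked table: occurrence
#' count, mean importance, and total (aggregated) importance per functional
#' group, ranked by total importance.
#'
#' @param records List of data frames from [extract_fragments()].
#' @return Data frame `fragment`, `count`, `mean_importance`,
#'   `total_importance`, sorted by `total_importance` descending.
#' @export
aggregate_fragments <- function(records) {
  all <- do.call(rbind, lapply(records, function(r) r[, c("fragment", "mean_importance")]))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(fragment = character(0), count = integer(0),
                      mean_importance = numeric(0), total_importance = numeric(0)))
  }
  agg <- stats::aggregate(mean_importance ~ fragment, all,
                          function(v) c(count = length(v), mean = mean(v), total = sum(v)))
  out <- data.frame(fragment = agg$fragment,
                    count = as.integer(agg$mean_importance[, "count"]),
                    mean_importance = agg$mean_importance[, "mean"],
                    total_importance = agg$mean_importance[, "total"])
  out[order(out$total_importance, decreasing = TRUE), , drop = FALSE]
}

#' Per-label fragment profile from correctly predicted molecules
#'
#' The per-label interpretability driver: selects up to `n_samples`
#' correctly predicted positive molecules (true positives) for the target
#' label, computes node importances (gradient attribution by default,
#' attention for GAT), extracts fragments and aggregates them.
#'
#' @param model A `trained_gnn`.
#' @param graphs List of `molecular_graph` objects (typically test set).
#' @param truth 0/1 label matrix aligned with `graphs`.
#' @param predictions 0/1 prediction matrix aligned with `graphs`.
#' @param label_index Target label.
#' @param n_samples Molecules to analyze (default 30; fewer with a warning
#'   when not enough correct predictions exist).
#' @param method `"gradient"` or `"attention"`.
#' @param library SMARTS library.
#' @return Ranked fragment table (see [aggregate_fragments()]); attribute
#'   `n_analyzed` records how many molecules entered the aggregate.
#' @export
fragment_profile <- function(model, graphs, truth, predictions, label_index,
                             n_samples = 30L,
                             method = c("gradient", "attention"),
                             library = smarts_library()) {
  method <- match.arg(method)
  truth <- as.matrix(unclass(truth)); predictions <- as.matrix(unclass(predictions))
  correct <- which(truth[, label_index] == 1 & predictions[, label_index] == 1)
  if (!length(correct)) {
    warning("no correctly predicted positives for this label; empty profile")
    out <- aggregate_fragments(list())
    attr(out, "n_analyzed") <- 0L
    return(out)
  }
  if (length(correct) < n_samples) {
    warning(sprintf("only %d correctly predicted positives available (requested %d)",
                    length(correct), n_samples))
  }
  use <- correct[seq_len(min(n_samples, length(correct)))]
  recs <- lapply(use, function(i) {
    imp <- if (method == "gradient") {
      gradient_node_importance(model, graphs[[i]], label_index)
    } else {
      attention_node_importance(model, graphs[[i]])
    }
    extract_fragments(graphs[[i]], imp, library)
  })
  out <- aggregate_fragments(recs)
  attr(out, "n_analyzed") <- length(use)
  out
}

#' Pearson correlation between two importance vectors
#'
#' @param a,b `node_importance` vectors for the same molecule (length >= 3).
#' @return Sample Pearson correlation, or `NA` (with a warning) when either
#'   vector has zero variance.
#' @export
importance_correlation <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in importance scores; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}
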