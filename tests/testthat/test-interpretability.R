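# Node attribution, fragment extraction and aggregation.

interp_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generation_config(40, seed = 50)
      smi <- generate_molecules(cfg)
      labels <- plant_labels(smi, cfg)
      graphs <- smiles_to_graphs(smi)
      gcfg <- gnn_config("gat", hidden_dim = 8, n_layers = 2, gat_heads = 2,
                         max_epochs = 5, patience = 5, seed = 8)
      cache <<- list(model = train_gnn(graphs, labels, gcfg, 1:32, 33:40),
                     graphs = graphs, labels = labels)
    }
    cache
  }
})

test_that("gradient importance is zero for a model with zeroed layers", {
  st <- interp_model()
  m0 <- st$model
  m0$params$conv <- lapply(m0$params$conv, function(cv) {
    lapply(cv, function(w) w * 0)
  })
  m0$params$head1$W <- m0$params$head1$W * 0
  imp <- gradient_node_importance(m0, st$graphs[[1]], 1)
  expect_true(all(imp == 0))
  expect_error(gradient_node_importance(st$model, st$graphs[[1]], 99),
               "out of range")
})

test_that("gradient importance is invariant to atom renumbering", {
  st <- interp_model()
  g1 <- smiles_to_graph("CCOC(C)=O")
  g2 <- smiles_to_graph("CC(=O)OCC")
  # atom correspondence: CCOC(C)=O atoms (C1 C2 O3 C4 C5 O6) appear in
  # CC(=O)OCC as (C5 C4 O6 C2 C1 O3) -> permutation by element role
  i1 <- gradient_node_importance(st$model, g1, 1)
  i2 <- gradient_node_importance(st$model, g2, 1)
  perm <- c(6, 5, 4, 2, 1, 3)
  expect_equal(as.numeric(i1), as.numeric(i2)[perm], tolerance = 1e-6)
  expect_true(all(as.numeric(i1) >= 0))
})

test_that("attention importance follows the layer/head-averaged formula", {
  st <- interp_model()
  # star molecule: central carbon with 3 neighbours (2-methylpropane)
  g <- smiles_to_graph("CC(C)C")
  zero_attention <- function(m) {
    for (l in seq_along(m$params$conv)) {
      m$params$conv[[l]]$a_src <- m$params$conv[[l]]$a_src * 0
      m$params$conv[[l]]$a_dst <- m$params$conv[[l]]$a_dst * 0
    }
    m
  }
  m <- zero_attention(st$model)   # uniform attention in every layer/head
  imp <- attention_node_importance(m, g)
  # center (atom 2): neighborhood of size 3 + self -> neighbour sum 3/4
  expect_equal(as.numeric(imp)[2], 3 / 4, tolerance = 1e-9)
  # leaves: one neighbour + self -> 1/2
  expect_equal(as.numeric(imp)[1], 1 / 2, tolerance = 1e-9)

  # identical per-layer attention: the 1/(L*H) normalization cancels L
  gcfg1 <- gnn_config("gat", hidden_dim = 8, n_layers = 1, gat_heads = 2,
                      max_epochs = 2, patience = 2, seed = 9)
  m1 <- zero_attention(train_gnn(st$graphs, st$labels, gcfg1, 1:32, 33:40))
  imp1 <- attention_node_importance(m1, g)
  expect_equal(as.numeric(imp), as.numeric(imp1), tolerance = 1e-9)

  # single atom: self-attention is 1, neighbour sum is empty
  g1 <- smiles_to_graph("C")
  att <- gnn_attention(m1, g1)
  expect_equal(att[[1]]$alpha, rep(1, 2))  # one alpha per head, both 1
  expect_equal(as.numeric(attention_node_importance(m1, g1)), 0)

  gcfg_gcn <- gnn_config("gcn", hidden_dim = 8, n_layers = 1, max_epochs = 2,
                         patience = 2, seed = 9)
  m_gcn <- train_gnn(st$graphs, st$labels, gcfg_gcn, 1:32, 33:40)
  expect_error(attention_node_importance(m_gcn, g), "GAT")
})

test_that("fragment extraction respects the percentile/tie convention and
           finds functional groups", {
  g <- smiles_to_graph("CCCCCC=O")  # hexanal
  # equal importances: every atom selected, one component, whole molecule
  fr_all <- extract_fragments(g, rep(1, 7))
  expect_equal(nrow(fr_all), 1)
  expect_equal(fr_all$n_atoms, 7)

  # importance concentrated on the carbonyl: component labelled aldehyde
  imp <- c(0, 0, 0, 0, 0, 1, 1)   # CHO carbon + oxygen
  fr <- extract_fragments(g, imp)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$fragment, "aldehyde")
  expect_setequal(fr$atoms[[1]], c(6, 7))

  # two disjoint hot regions -> two records
  g2 <- smiles_to_graph("OCCCCCCO")
  fr2 <- extract_fragments(g2, c(1, 1, 0, 0, 0, 0, 1, 1))
  expect_equal(nrow(fr2), 2)
  expect_error(extract_fragments(g, rep(1, 3)), "length")
})

test_that("fragment atom sets are connected and mutually disjoint", {
  set.seed(51)
  graphs <- shared_fixture()$graphs[1:100]
  for (g in graphs) {
    n <- nrow(g$node_features)
    fr <- extract_fragments(g, runif(n))
    atoms <- unlist(fr$atoms)
    expect_equal(anyDuplicated(atoms), 0)
    # connectivity: BFS inside each reported set must reach every member
    for (set in fr$atoms) {
      if (length(set) == 1) next
      reach <- set[1]; frontier <- set[1]
      while (length(frontier)) {
        nxt <- unique(g$edge_index[g$edge_index[, 1] %in% frontier, 2])
        frontier <- setdiff(intersect(nxt, set), reach)
        reach <- c(reach, frontier)
      }
      expect_setequal(reach, set)
    }
  }
})

test_that("aggregation ranks fragments and the per-label profile flags
           shortages", {
  recs <- list(
    data.frame(fragment = c("ester", "methyl"), n_atoms = c(4, 1),
               mean_importance = c(0.9, 0.2), atoms = I(list(1:4, 5))),
    data.frame(fragment = "ester", n_atoms = 4,
               mean_importance = 0.7, atoms = I(list(2:5))))
  agg <- aggregate_fragments(recs)
  expect_equal(agg$fragment[1], "ester")
  expect_equal(agg$count[agg$fragment == "ester"], 2L)
  expect_equal(agg$total_importance[agg$fragment == "ester"], 1.6)
  expect_equal(agg$mean_importance[agg$fragment == "ester"], 0.8)

  st <- interp_model()
  y <- unclass(st$labels)
  pred <- matrix(1L, nrow(y), ncol(y))
  expect_warning(
    prof <- fragment_profile(st$model, st$graphs, y, pred, 1, n_samples = 30),
    "only")
  expect_s3_class(prof, "data.frame")
  # no correct positives at all -> empty table with warning
  expect_warning(
    empty <- fragment_profile(st$model, st$graphs, y * 0L, pred, 1),
    "no correctly predicted")
  expect_equal(nrow(empty), 0)
})

test_that("importance correlation follows the textbook Pearson formula", {
  expect_equal(importance_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(importance_correlation(c(1, 2, 3, 4), 10 - c(1, 2, 3, 4)), -1)
  expect_equal(importance_correlation(1:5, c(2, 4, 5, 4, 5)),
               6 / sqrt(10 * 6), tolerance = 1e-12)
  expect_warning(r <- importance_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(r))
})
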