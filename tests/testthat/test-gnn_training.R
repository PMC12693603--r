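# Training-loop contracts: overfitting sanity, determinism, permutation
# invariance of graph-level predictions, accessors.

small_train_setup <- function(n = 40, seed = 11) {
  cfg <- generation_config(n, seed = seed)
  smi <- generate_molecules(cfg)
  list(smiles = smi, labels = plant_labels(smi, cfg),
       graphs = smiles_to_graphs(smi))
}

test_that("a small GCN overfits a tiny dataset and training is deterministic", {
  st <- small_train_setup()
  cfg <- gnn_config("gcn", hidden_dim = 16, n_layers = 2, max_epochs = 40,
                    patience = 40, dropout_rate = 0, batch_size = 8, seed = 3)
  m1 <- train_gnn(st$graphs, st$labels, cfg, train_idx = 1:30, val_idx = 31:40)
  expect_lt(utils::tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_gnn(st$graphs, st$labels, cfg, train_idx = 1:30, val_idx = 31:40)
  expect_identical(m1$history, m2$history)
  expect_equal(predict(m1, st$graphs), predict(m2, st$graphs))
  expect_error(train_gnn(st$graphs, st$labels, cfg, integer(0), 31:40),
               "empty")
})

test_that("scores are sigmoid probabilities and embeddings have hidden width", {
  st <- small_train_setup(30, seed = 12)
  for (arch in c("gcn", "gat", "nnconv")) {
    cfg <- gnn_config(arch, hidden_dim = 8, n_layers = 2, gat_heads = 2,
                      max_epochs = 4, patience = 4, seed = 4, edge_hidden = 3)
    m <- train_gnn(st$graphs, st$labels, cfg, 1:24, 25:30)
    sc <- predict(m, st$graphs[1:5])
    expect_true(all(sc > 0 & sc < 1))
    expect_equal(colnames(sc), colnames(st$labels))
    emb <- predict(m, st$graphs[1:5], type = "embeddings")
    expect_equal(dim(emb), c(5, 8))
  }
})

test_that("graph-level predictions are invariant to atom reordering", {
  # same molecules written with different atom orders
  pairs <- list(c("CCOC(C)=O", "CC(=O)OCC"),
                c("CCO", "OCC"),
                c("Cc1ccccc1", "c1ccccc1C"))
  st <- small_train_setup(30, seed = 13)
  for (arch in c("gcn", "gat", "nnconv")) {
    cfg <- gnn_config(arch, hidden_dim = 8, n_layers = 2, gat_heads = 2,
                      max_epochs = 3, patience = 3, seed = 5, edge_hidden = 3)
    m <- train_gnn(st$graphs, st$labels, cfg, 1:24, 25:30)
    for (pr in pairs) {
      s <- predict(m, smiles_to_graphs(pr))
      expect_equal(s[1, ], s[2, ], tolerance = 1e-5,
                   info = paste(arch, pr[1]))
    }
  }
})

test_that("GAT attention accessor returns one alpha per directed edge plus
           self-loop, per layer and head", {
  st <- small_train_setup(24, seed = 14)
  cfg <- gnn_config("gat", hidden_dim = 8, n_layers = 2, gat_heads = 2,
                    max_epochs = 2, patience = 2, seed = 6)
  m <- train_gnn(st$graphs, st$labels, cfg, 1:18, 19:24)
  g <- st$graphs[[1]]
  att <- gnn_attention(m, g)
  expect_length(att, 2)
  n <- nrow(g$node_features); e <- nrow(g$edge_index)
  for (l in 1:2) {
    expect_equal(nrow(att[[l]]), 2 * (e + n))  # 2 heads x (edges + self-loops)
    sums <- stats::aggregate(alpha ~ dst + head, att[[l]], sum)
    expect_true(all(abs(sums$alpha - 1) < 1e-6))
  }
  cfg2 <- gnn_config("gcn", hidden_dim = 8, n_layers = 1, max_epochs = 2,
                     patience = 2, seed = 6)
  m2 <- train_gnn(st$graphs, st$labels, cfg2, 1:18, 19:24)
  expect_error(gnn_attention(m2, g), "GAT")
})

test_that("training history records the plateau learning-rate decay", {
  st <- small_train_setup(30, seed = 15)
  cfg <- gnn_config("gcn", hidden_dim = 4, n_layers = 1, max_epochs = 30,
                    patience = 30, lr_patience = 3, lr_factor = 0.5, seed = 7)
  m <- train_gnn(st$graphs, st$labels, cfg, 1:24, 25:30)
  expect_true(all(diff(m$history$lr) <= 0))
  expect_true(is.finite(m$best_val_f1))
})
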