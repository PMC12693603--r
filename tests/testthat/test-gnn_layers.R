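# Layer-level contracts: hand-evaluated message passing, attention
# normalization, and full backward passes verified against numerical
# gradients.

test_that("GCN: isolated node with identity weights is passed through", {
  x <- matrix(c(1, -2, 3), 1)
  out <- gcn_layer(x, matrix(integer(0), 0, 2), diag(3))
  expect_equal(out, x)   # self-loop coefficient 1/(0+1) = 1
})

test_that("GCN: two connected nodes average per the normalization formula", {
  x <- rbind(c(1, 0), c(0, 1))            # e1, e2
  ei <- rbind(c(1L, 2L), c(2L, 1L))       # one bond, both directions
  out <- gcn_layer(x, ei, diag(2))
  # d=1 for both: self 1/2, edge 1/sqrt(2*2) = 1/2 -> (own + other) / 2
  expect_equal(out, rbind(c(0.5, 0.5), c(0.5, 0.5)))
})

test_that("GCN layer is permutation-equivariant", {
  set.seed(1)
  g <- smiles_to_graph("CCOC(C)=O")
  W <- matrix(rnorm(25 * 4), 25, 4)
  out <- gcn_layer(g$node_features, g$edge_index, W)
  perm <- sample(nrow(g$node_features))
  inv <- order(perm)
  x_p <- g$node_features[perm, ]
  ei_p <- matrix(inv[g$edge_index], ncol = 2)
  out_p <- gcn_layer(x_p, ei_p, W)
  expect_equal(out_p[inv, ], out, tolerance = 1e-12)
})

test_that("GAT: attention normalizes over each neighborhood, uniform for
           identical features, and 1 for a singleton", {
  set.seed(2)
  g <- smiles_to_graph("CC(C)(C)O")   # branched: varied degrees
  heads <- 2L
  wts <- list(W = matrix(rnorm(25 * 6, sd = 0.3), 25, 6),
              a_src = matrix(rnorm(3 * heads), 3, heads),
              a_dst = matrix(rnorm(3 * heads), 3, heads))
  res <- gat_layer(g$node_features, g$edge_index, wts, heads = heads)
  att <- res$attention
  sums <- stats::aggregate(alpha ~ dst + head, att, sum)
  expect_true(all(abs(sums$alpha - 1) < 1e-6))

  # identical node features -> equal logits -> uniform attention
  x_same <- matrix(1, nrow(g$node_features), 25)
  res2 <- gat_layer(x_same, g$edge_index, wts, heads = heads)
  att2 <- res2$attention
  nb_count <- table(att2$dst[att2$head == 1])
  for (d in as.integer(names(nb_count))) {
    a <- att2$alpha[att2$dst == d & att2$head == 1]
    expect_equal(a, rep(1 / length(a), length(a)), tolerance = 1e-9)
  }

  single <- gat_layer(matrix(rnorm(25), 1), matrix(integer(0), 0, 2),
                      list(W = matrix(rnorm(25 * 3), 25, 3),
                           a_src = matrix(rnorm(3), 3, 1),
                           a_dst = matrix(rnorm(3), 3, 1)), heads = 1L)
  expect_equal(single$attention$alpha, 1)
})

test_that("NNConv: zero edge network leaves only the root transform; hand-set
           edge transform reproduces the matrix-vector message", {
  g <- smiles_to_graph("CC")
  d_in <- 25L; d_out <- 3L
  wts0 <- list(W_root = matrix(rnorm(d_in * d_out, sd = 0.1), d_in, d_out),
               b = rep(0, d_out),
               W1 = matrix(0, 6, 2), b1 = rep(0, 2),
               W2 = matrix(0, 2, d_in * d_out), b2 = rep(0, d_in * d_out))
  out0 <- nnconv_layer(g$node_features, g$edge_index, g$edge_features, wts0)
  expect_equal(out0, g$node_features %*% wts0$W_root)

  # Theta fixed through b2: message = Theta^T h_src, mean over the single
  # incoming edge
  set.seed(3)
  Theta <- matrix(rnorm(d_in * d_out), d_in, d_out)
  wts1 <- wts0; wts1$b2 <- as.numeric(Theta)
  out1 <- nnconv_layer(g$node_features, g$edge_index, g$edge_features, wts1)
  manual1 <- g$node_features[2, , drop = FALSE] %*% Theta  # node 1 receives from 2
  expect_equal(out1[1, ], (g$node_features %*% wts1$W_root)[1, ] + manual1[1, ],
               tolerance = 1e-12)
  # symmetric edge features -> both directions carry the same transform
  manual2 <- g$node_features[1, , drop = FALSE] %*% Theta
  expect_equal(out1[2, ], (g$node_features %*% wts1$W_root)[2, ] + manual2[1, ],
               tolerance = 1e-12)
  expect_error(nnconv_layer(g$node_features, g$edge_index, NULL, wts1),
               "edge_features")
})

test_that("backward passes match numerical gradients for all architectures", {
  set.seed(4)
  graphs <- smiles_to_graphs(c("CCO", "c1ccccc1C=O", "CC(=O)OC"))
  y <- matrix(rbinom(9, 1, 0.5), 3, 3)
  batch <- odorgraph:::.build_batch(graphs)
  h <- 1e-5
  for (arch in c("gcn", "gat", "nnconv")) {
    cfg <- gnn_config(arch, hidden_dim = 6, n_layers = 2, gat_heads = 2,
                      dropout_rate = 0, batch_norm = TRUE, seed = 5,
                      edge_hidden = 3)
    set.seed(5)
    params <- odorgraph:::.init_params(cfg, 25, 3)
    fwd <- odorgraph:::.gnn_forward(batch, params, cfg, train = FALSE)
    lg <- odorgraph:::.loss_grad("focal", fwd$logits, y, 0.25, 2)
    bk <- odorgraph:::.gnn_backward(fwd, batch, params, cfg, lg$dlogits)
    loss_at <- function(p) {
      f <- odorgraph:::.gnn_forward(batch, p, cfg, train = FALSE)
      odorgraph:::.loss_grad("focal", f$logits, y, 0.25, 2)$loss
    }
    leaves <- list(c("conv", 1, 1), c("conv", 2, 2), c("head1", 1),
                   c("head2", 1), c("bn", 1, 1), c("bn", 2, 2))
    for (pt in leaves) {
      leaf <- params; gleaf <- bk$grads
      for (q in pt) { leaf <- leaf[[q]]; gleaf <- gleaf[[q]] }
      for (i in sample(length(leaf), min(3, length(leaf)))) {
        bump <- function(delta) {
          p <- params
          if (length(pt) == 2) p[[pt[1]]][[as.integer(pt[2])]][i] <-
              p[[pt[1]]][[as.integer(pt[2])]][i] + delta
          else p[[pt[1]]][[as.integer(pt[2])]][[as.integer(pt[3])]][i] <-
              p[[pt[1]]][[as.integer(pt[2])]][[as.integer(pt[3])]][i] + delta
          p
        }
        num <- (loss_at(bump(h)) - loss_at(bump(-h))) / (2 * h)
        expect_equal(gleaf[i], num, tolerance = 1e-4,
                     info = paste(arch, paste(pt, collapse = "/"), i))
      }
    }
    # input gradient (used by gradient attribution)
    i <- 11
    b1 <- batch; b1$X[i] <- b1$X[i] + h
    b2 <- batch; b2$X[i] <- b2$X[i] - h
    f1 <- odorgraph:::.gnn_forward(b1, params, cfg, FALSE)
    f2 <- odorgraph:::.gnn_forward(b2, params, cfg, FALSE)
    num <- (odorgraph:::.loss_grad("focal", f1$logits, y, 0.25, 2)$loss -
            odorgraph:::.loss_grad("focal", f2$logits, y, 0.25, 2)$loss) / (2 * h)
    expect_equal(bk$dX[i], num, tolerance = 1e-4, info = arch)
  }
})
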