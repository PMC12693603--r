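# Atom/bond featurization and molecular-graph assembly.

test_that("methane carbon matches the reference toolkit atom description", {
  v <- featurize_atom("C", 1)
  expect_length(v, 25)
  expect_equal(unname(v["id_C"]), 1)
  expect_equal(sum(v[paste0("id_", atom_vocabulary())]), 1)
  expect_equal(unname(v["atomic_number"]), 6)
  expect_equal(unname(v["formal_charge"]), 0)
  expect_equal(unname(v["implicit_h"]), 4)
  expect_equal(unname(v["aromatic"]), 0)
  expect_equal(unname(v["degree"]), 0)
  expect_equal(unname(sum(v[c("ring_any", "ring_3", "ring_4", "ring_5", "ring_6")])), 0)
})

test_that("benzene carbons are aromatic sp2 ring atoms of degree 2", {
  g <- smiles_to_graph("c1ccccc1")
  expect_equal(nrow(g$node_features), 6)
  for (i in 1:6) {
    v <- g$node_features[i, ]
    expect_equal(unname(v["aromatic"]), 1)
    expect_equal(unname(v["ring_any"]), 1)
    expect_equal(unname(v["ring_6"]), 1)
    expect_equal(unname(v["degree"]), 2)
    expect_equal(unname(v["hyb_sp2"]), 1)
  }
})

test_that("bond features follow the frozen 6-slot layout", {
  b <- featurize_bond("CC", 1)
  expect_length(b, 6)
  expect_equal(unname(b["bond_single"]), 1)
  expect_equal(unname(b["conjugated"]), 0)
  expect_equal(unname(b["in_ring"]), 0)
  g <- smiles_to_graph("c1ccccc1")
  for (r in seq_len(nrow(g$edge_features))) {
    expect_equal(unname(g$edge_features[r, "bond_aromatic"]), 1)
    expect_equal(unname(g$edge_features[r, "conjugated"]), 1)
    expect_equal(unname(g$edge_features[r, "in_ring"]), 1)
  }
})

test_that("graph shapes: n nodes, 2m directed edges, symmetric edge set", {
  g <- smiles_to_graph("CCO")
  expect_equal(nrow(g$node_features), 3)
  expect_equal(nrow(g$edge_index), 4)
  expect_equal(nrow(smiles_to_graph("c1ccccc1")$edge_index), 12)
  # symmetry: both directed copies present with identical features
  key <- paste(g$edge_index[, 1], g$edge_index[, 2])
  rev_key <- paste(g$edge_index[, 2], g$edge_index[, 1])
  expect_setequal(key, rev_key)
  for (r in seq_len(nrow(g$edge_index))) {
    mate <- which(key == rev_key[r])
    expect_equal(g$edge_features[r, ], g$edge_features[mate, ])
  }
})

test_that("parse and vocabulary errors are raised and lenient mode skips", {
  expect_error(smiles_to_graph("not_a_smiles"), "cannot parse")
  expect_error(smiles_to_graph("CC[Si](C)C"), "unsupported element")
  expect_warning(out <- smiles_to_graph("CC[Si](C)C", on_unsupported = "skip"),
                 "skipping")
  expect_null(out)
  expect_warning(gs <- smiles_to_graphs(c("CCO", "CC[Si](C)C"),
                                        on_unsupported = "skip"))
  expect_length(gs, 1)
  expect_equal(attr(gs, "kept"), 1L)
})

test_that("featurization is permutation-equivariant", {
  # same molecule written with two atom orders; known correspondence
  g1 <- smiles_to_graph("CCO")   # C1 C2 O3
  g2 <- smiles_to_graph("OCC")   # O1 C2 C3
  perm <- c(3, 2, 1)             # g1 atom i == g2 atom perm[i]
  expect_equal(unname(g1$node_features), unname(g2$node_features[perm, ]))

  g3 <- smiles_to_graph("CC(=O)OCC")  # ethyl acetate, acyl-first
  g4 <- smiles_to_graph("CCOC(C)=O")  # ethyl acetate, alkoxy-first
  # permutation-invariant summaries must agree
  expect_equal(sort(colSums(g3$node_features)), sort(colSums(g4$node_features)))
  expect_equal(sort(colSums(g3$edge_features)), sort(colSums(g4$edge_features)))
})

test_that("hydrogens are implicit and one-hot blocks respect their bounds", {
  gs <- shared_fixture()$graphs[1:100]
  for (g in gs) {
    x <- g$node_features
    expect_true(all(x[, "atomic_number"] != 1))
    expect_true(all(rowSums(x[, paste0("id_", atom_vocabulary()), drop = FALSE]) == 1))
    expect_true(all(rowSums(x[, c("hyb_sp", "hyb_sp2", "hyb_sp3"), drop = FALSE]) <= 1))
    if (nrow(g$edge_features)) {
      bt <- g$edge_features[, c("bond_single", "bond_double", "bond_triple",
                                "bond_aromatic"), drop = FALSE]
      expect_true(all(rowSums(bt) == 1))
    }
  }
})

test_that("atom features agree with the rdkit oracle on generated molecules", {
  expect_true(rdkit_available())
  smi <- unique(shared_fixture()$smiles)[1:60]
  ora <- rdkit_oracle(smi)
  for (i in seq_along(smi)) {
    o <- ora[[i]]
    if (is.null(o)) next
    g <- smiles_to_graph(smi[i])
    x <- g$node_features
    expect_equal(unname(x[, "atomic_number"]), as.numeric(o$z), info = smi[i])
    expect_equal(unname(x[, "formal_charge"]), as.numeric(o$charge), info = smi[i])
    expect_equal(unname(x[, "degree"]), as.numeric(o$degree), info = smi[i])
    expect_equal(unname(x[, "aromatic"]), as.numeric(o$aromatic), info = smi[i])
    expect_equal(unname(x[, "explicit_h"] + x[, "implicit_h"]),
                 as.numeric(o$total_h), info = smi[i])
    expect_equal(unname(x[, "ring_any"]), as.numeric(o$in_ring), info = smi[i])
    expect_equal(unname(x[, "ring_5"]), as.numeric(o$ring5), info = smi[i])
    expect_equal(unname(x[, "ring_6"]), as.numeric(o$ring6), info = smi[i])
    expect_equal(nrow(g$edge_index), 2 * o$n_bonds, info = smi[i])
  }
})
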