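# Synthetic molecule generation, planted labels and the descriptor table.

test_that("generation is deterministic and restrictable to a single scaffold", {
  cfg <- generation_config(100, seed = 7)
  expect_identical(generate_molecules(cfg), generate_molecules(cfg))

  # degenerate grammar: one undecorated scaffold
  grammar <- list(scaffolds = list(chain3 = list(weight = 1)),
                  decorations = c(), decoration_weights = c(),
                  max_decorations = 0L)
  out <- generate_molecules(generation_config(3, seed = 1), grammar)
  expect_identical(out, rep("CCC", 3))
})

test_that("generated molecules are valid and stay inside the element vocabulary", {
  cfg <- generation_config(500, seed = 1)
  smi <- generate_molecules(cfg)
  mols <- odorgraph:::parse_mols(smi)   # round-trip through the toolkit parser
  expect_length(mols, 500)
  els <- unique(unlist(lapply(mols, function(m) m$element)))
  expect_true(all(els %in% atom_vocabulary()))
  expect_true(rdkit_available())
  ora <- rdkit_oracle(unique(smi))
  ok <- !vapply(ora, is.null, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("planted labels follow the rules deterministically at act=1, bg=0", {
  rules <- list(fruity = list(smarts = "[CX3](=O)[OX2][#6]",
                              activation = 1, background = 1e-12),
                other = list(smarts = "[SX2H]", activation = 1,
                             background = 1e-12))
  cfg <- generation_config(2, seed = 1, label_names = c("fruity", "other"),
                           rule_table = rules)
  y <- plant_labels(c("CCOC(C)=O", "C"), cfg)
  expect_equal(unname(y[1, "fruity"]), 1L)  # ethyl acetate is an ester
  expect_equal(unname(y[2, "fruity"]), 0L)  # methane is not
})

test_that("realized positive rate matches the analytic mixture rate", {
  cfg0 <- generation_config(2000, seed = 3)
  smi <- generate_molecules(cfg0)
  rules <- list(fruity = list(smarts = "[CX3](=O)[OX2][#6]",
                              activation = 0.9, background = 0.05),
                green = list(smarts = "[CX3H1]=O", activation = 0.9,
                             background = 0.05))
  cfg <- generation_config(2000, seed = 3, label_names = names(rules),
                           rule_table = rules)
  y <- plant_labels(smi, cfg)
  # independent match fractions from the OpenBabel SMARTS engine
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smi, sprintf("m%d", seq_along(smi)))))
  for (k in seq_along(rules)) {
    cnt <- suppressWarnings(ChemmineR::smartsSearchOB(sdf, rules[[k]]$smarts,
                                                      uniqueMatches = FALSE))
    m <- mean(cnt > 0)
    expected <- m * 0.9 + (1 - m) * 0.05
    expect_lt(abs(mean(y[, k]) - expected), 0.03)
  }
})

test_that("label frequency is monotone in the activation probability", {
  cfg0 <- generation_config(800, seed = 5)
  smi <- generate_molecules(cfg0)
  freqs <- vapply(c(0.3, 0.6, 0.9), function(act) {
    rules <- list(fruity = list(smarts = "[CX3](=O)[OX2][#6]",
                                activation = act, background = 0.05),
                  other = list(smarts = "[SX2]", activation = act,
                               background = 0.05))
    cfg <- generation_config(800, seed = 5, label_names = names(rules),
                             rule_table = rules)
    mean(plant_labels(smi, cfg)[, "fruity"])
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
})

test_that("descriptor table has clean structural columns and tiered noise", {
  smi <- shared_fixture()$smiles
  clean <- synth_descriptor_table(
    smi, descriptor_noise_spec(n_descriptors = 30,
                               missing_tier_fractions = c(0, 0, 0),
                               outlier_rate = 0), seed = 2)
  expect_false(anyNA(clean))
  expect_equal(unname(synth_descriptor_table(
    "CCO", descriptor_noise_spec(n_descriptors = 12,
                                 missing_tier_fractions = c(0, 0, 0),
                                 outlier_rate = 0), seed = 1)[1, "heavy_atom_count"]), 3)

  heavy <- synth_descriptor_table(
    smi, descriptor_noise_spec(n_descriptors = 200,
                               missing_tier_fractions = c(0, 0, 0.2),
                               outlier_rate = 0), seed = 4)
  high_missing <- mean(colMeans(is.na(heavy)) > 0.30)
  expect_lt(abs(high_missing - 0.2), 0.06)
})

test_that("a decision stump on the rule-match column separates noiseless labels", {
  smi <- shared_fixture()$smiles
  rules <- lapply(default_rule_table(), function(r) {
    r$activation <- 1; r$background <- 1e-12; r
  })
  cfg <- generation_config(length(smi), seed = 9, rule_table = rules)
  y <- plant_labels(smi, cfg)
  d <- synth_descriptor_table(smi, descriptor_noise_spec(
    n_descriptors = 20, missing_tier_fractions = c(0, 0, 0),
    outlier_rate = 0), seed = 9, rule_table = rules)
  for (lb in colnames(y)) {
    pred <- as.integer(d[, paste0("rule_match_", lb)] >= 0.5)
    expect_equal(brute_force_f1(y[, lb], pred),
                 if (any(y[, lb] == 1)) 1 else 0)
  }
})

test_that("study files are written row-aligned", {
  fx <- shared_fixture()
  dir <- withr::local_tempdir()
  d <- synth_descriptor_table(fx$smiles[1:20], descriptor_noise_spec(
    n_descriptors = 15, missing_tier_fractions = c(0, 0, 0),
    outlier_rate = 0), seed = 1)
  paths <- write_synthetic_csv(fx$smiles[1:20], fx$labels[1:20, ], dir, d)
  mols <- utils::read.csv(file.path(dir, "molecules.csv"), check.names = FALSE)
  expect_equal(nrow(mols), 20)
  expect_equal(names(mols)[1], "smiles")
  expect_equal(nrow(utils::read.csv(file.path(dir, "descriptors.csv"))), 20)
})
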