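test_that("small molecules produce the expected graph shapes", {
  g <- smiles_to_graph("CC")
  expect_equal(g$node_count, 2)
  expect_equal(nrow(g$edges), 2)          # one bond, both directions
  expect_equal(nrow(g$bonds), 1)

  b <- smiles_to_graph("c1ccccc1")
  expect_equal(b$node_count, 6)
  expect_equal(nrow(b$edges), 12)
  expect_true(all(b$bonds$bond_type == "aromatic"))
  aschema <- atom_feature_schema()
  off <- planet:::schema_offsets(aschema)
  arom_col <- off[8] + 2                  # "1" inside the aromaticity block
  ring_col <- off[9] + 2
  expect_true(all(b$node_features[, arom_col] == 1))
  expect_true(all(b$node_features[, ring_col] == 1))
})

test_that("invalid inputs raise parse errors carrying the input", {
  expect_error(smiles_to_graph("not_a_smiles"), "not_a_smiles")
  expect_error(smiles_to_graph(""), "non-empty")
})

test_that("atom encoding enforces the closed vocabularies", {
  v <- encode_atom(list(atomic_num = 6, chirality = "unspecified", degree = 4,
                        formal_charge = 0, num_hs = 0, num_radical_e = 0,
                        hybridization = "sp3", aromatic = 0, in_ring = 0))
  expect_equal(sum(v), 9)
  expect_length(v, sum(atom_feature_schema()$sizes))
  expect_error(encode_atom(list(atomic_num = 120, chirality = "unspecified",
                                degree = 0, formal_charge = 0, num_hs = 0,
                                num_radical_e = 0, hybridization = "sp3",
                                aromatic = 0, in_ring = 0)),
               "atomic_num")
  v2 <- encode_atom(list(atomic_num = 6, chirality = "unspecified", degree = 1,
                         formal_charge = -5, num_hs = 3, num_radical_e = 0,
                         hybridization = "sp3", aromatic = 0, in_ring = 0))
  off <- planet:::schema_offsets(atom_feature_schema())
  expect_equal(which(v2[(off[4] + 1):(off[4] + 11)] == 1), 1)  # -5 first
})

test_that("validate_graph reports planted invariant violations", {
  g <- smiles_to_graph("CCO")
  expect_length(validate_graph(g), 0)

  broken <- g
  broken$edges <- broken$edges[-2, , drop = FALSE]   # drop one reverse edge
  broken$edge_features <- broken$edge_features[-2, , drop = FALSE]
  broken$bond_id <- broken$bond_id[-2]
  expect_match(paste(validate_graph(broken), collapse = " "),
               "bidirectionality")

  broken2 <- g
  broken2$node_features[1, 1:119] <- 0               # zero one block
  expect_match(paste(validate_graph(broken2), collapse = " "), "one-hot")
})

test_that("featurization is deterministic", {
  g1 <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  g2 <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(g1$node_features, g2$node_features)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$edge_features, g2$edge_features)
})

test_that("descriptors match the reference parser on representative chemistry", {
  smiles <- c("CC(=O)Oc1ccccc1C(=O)O", "Nc1ccc2ccccc2c1", "Oc1ccncc1",
              "CC(C)Cc1ccc(Cl)cc1", "c1ccc2[nH]ccc2c1", "O=C1CCCCC1",
              "FC(F)(F)c1ccccc1")
  refs <- rdkit_reference(smiles, "smiles")
  for (i in seq_along(smiles)) {
    bad <- compare_with_reference(smiles_to_graph(smiles[i]), refs[[i]])
    expect_length(bad, 0)
  }
})

test_that("one-hot blocks and bidirectionality hold across fixture molecules", {
  bm <- bench_easy()
  for (g in bm$dataset$graphs[seq(1, 80, by = 7)]) {
    expect_length(validate_graph(g), 0)
  }
})
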