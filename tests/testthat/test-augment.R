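test_that("unit edge coefficients leave predictions bit-identical", {
  fp <- random_model(seed = 41)
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  p0 <- predict_ligand_only(g, fp)$probability
  gr <- edge_gradients(g, fp, label = 1)          # instruments the forward
  expect_identical(predict_ligand_only(g, fp)$probability, p0)
  expect_equal(nrow(gr), nrow(g$bonds))           # one gradient per bond
})

test_that("a flat loss yields zero bond gradients", {
  fp <- random_model(seed = 42)
  fp$lig_clf_w[] <- 0; fp$lig_clf_b <- 0
  gr <- edge_gradients(smiles_to_graph("CCO"), fp, label = 1)
  expect_equal(gr$gradient, c(0, 0))
})

test_that("automorphic bonds receive equal gradients", {
  fp <- random_model(seed = 43)
  gr <- edge_gradients(smiles_to_graph("c1ccccc1"), fp, label = 1)
  expect_lt(max(gr$gradient) - min(gr$gradient), 1e-6)
})

test_that("selection honours the sign rule and the distance bound", {
  ex <- model_with_negative_gradients()
  g <- ex$graph
  ref <- planet:::scaffold_ref(g)

  res <- select_and_delete(g, ex$grads, ref, mu = 1.0)
  expect_s3_class(res, "augmentation_result")
  expect_equal(nrow(res$augmented$bonds), nrow(g$bonds) - 1)
  expect_lt(res$gradient, 0)
  expect_length(validate_graph(res$augmented), 0)

  pos <- ex$grads; pos$gradient <- abs(pos$gradient)  # all gradients >= 0
  expect_null(select_and_delete(g, pos, ref, mu = 1.0))

  # mu = 0 with every deletion strictly away from the scaffold
  dists <- vapply(seq_len(nrow(g$bonds)), function(b) {
    scaffold_distance(planet:::delete_bond(g, b), ref)
  }, numeric(1))
  expect_true(all(dists > 0))
  expect_null(select_and_delete(g, ex$grads, ref, mu = 0))
})

test_that("the selected bond matches a brute-force search on small molecules", {
  ex <- model_with_negative_gradients()
  smalls <- c("OC(=O)Cc1ccccc1", "Cc1ccc(O)cc1", "Clc1ccccc1C",
              "OCc1ccncc1")
  for (s in smalls) {
    g <- smiles_to_graph(s)
    expect_lte(nrow(g$bonds), 12)
    gr <- edge_gradients(g, ex$params, label = 1)
    ref <- planet:::scaffold_ref(g)
    mu <- 0.9
    res <- select_and_delete(g, gr, ref, mu)
    # brute force: every single-bond deletion, keep those within mu,
    # pick the most negative gradient, ties by lower bond index
    ok <- vapply(seq_len(nrow(g$bonds)), function(b) {
      gr$gradient[b] < 0 &&
        scaffold_distance(planet:::delete_bond(g, b), ref) <= mu
    }, logical(1))
    if (!any(ok)) {
      expect_null(res)
    } else {
      cand <- which(ok)
      best <- cand[order(gr$gradient[cand], cand)][1]
      expect_equal(res$bond, best, info = s)
    }
  }
})

test_that("batch augmentation partitions actives into successes and skips", {
  ex <- model_with_negative_gradients()
  mu <- calibrate_mu(ex$actives)
  ab <- augment_batch(ex$actives, ex$params, mu)
  expect_equal(length(ab$augmented) + ab$skipped, length(ex$actives))
  expect_gt(length(ab$augmented), 0)
  for (r in ab$augmented) {
    expect_equal(nrow(r$augmented$bonds), nrow(r$original$bonds) - 1)
    expect_lt(r$gradient, 0)
    expect_lte(r$distance, as.numeric(mu))
  }
  # nothing qualifies at mu = 0 for these decorated molecules
  ab0 <- augment_batch(ex$actives, ex$params, 0)
  expect_length(ab0$augmented, 0)
  expect_equal(ab0$skipped, length(ex$actives))
})

test_that("augmented graphs can be exported back to SMILES", {
  ex <- model_with_negative_gradients()
  res <- select_and_delete(ex$graph, ex$grads, planet:::scaffold_ref(ex$graph),
                           mu = 1.0)
  smi <- graph_to_smiles(res$augmented)
  expect_true(is.na(smi) || nzchar(smi))
  expect_equal(smarts_matches("CC(=O)O", "C(=O)O"), 1)
})
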