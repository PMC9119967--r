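test_that("curation removes duplicates and variably labelled molecules", {
  toy <- data.frame(smiles = c("CCO", "CCO", "CCN"),
                    label = c("active", "active", "decoy"))
  cu <- curate(toy)
  expect_equal(cu$report$duplicates_removed, 1)
  expect_equal(cu$report$output_records, 2)

  toy2 <- data.frame(smiles = c("CCO", "CCO", "CCN"),
                     label = c("active", "decoy", "decoy"))
  cu2 <- curate(toy2)
  expect_equal(cu2$report$variably_labeled_molecules, 1)
  expect_equal(cu2$report$variably_labeled_records_removed, 2)
  expect_equal(cu2$report$output_records, 1)
  expect_equal(cu2$records$smiles, "CCN")

  # spelling variants collapse through canonicalization
  toy3 <- data.frame(smiles = c("OCC", "CCO"), label = c("active", "active"))
  expect_equal(curate(toy3)$report$duplicates_removed, 1)
})

test_that("curation is idempotent and conserves records exactly", {
  bm <- bench_easy()
  fx <- generate_duplicates_fixture(bm$dataset$records[, c("smiles", "label")],
                                    n_dups = 7, n_conflicts = 3, seed = 5)
  fx$records <- rbind(fx$records,
                      data.frame(smiles = "not_a_smiles", label = "decoy"))
  cu <- curate(fx$records)
  r <- cu$report
  expect_equal(r$input_records,
               r$output_records + r$unparseable_removed +
                 r$duplicates_removed + r$variably_labeled_records_removed)
  cu2 <- curate(cu$records[, c("smiles", "label")])
  expect_equal(cu2$report$duplicates_removed, 0)
  expect_equal(cu2$report$variably_labeled_records_removed, 0)
  expect_equal(cu2$records$canonical, cu$records$canonical)
})

test_that("stratified splitting is deterministic and partitions per class", {
  smiles <- c(sprintf("C%sO", strrep("C", 1:50)), sprintf("N%s", strrep("C", 1:50)))
  ds <- as_tli_dataset("t", smiles, rep(c("active", "decoy"), each = 50),
                       build_graphs = FALSE)
  s1 <- split_dataset(ds, 0.10, seed = 3)
  s2 <- split_dataset(ds, 0.10, seed = 3)
  expect_identical(s1$records$split, s2$records$split)
  tab <- table(s1$records$label, s1$records$split)
  expect_equal(as.integer(tab["active", "test"]), 5)
  expect_equal(as.integer(tab["decoy", "test"]), 5)
  expect_false(any(is.na(s1$records$split)))
  tiny <- as_tli_dataset("t", c("CCO", "CCN"), c("active", "decoy"),
                         build_graphs = FALSE)
  expect_error(split_dataset(tiny), "fewer than 2")
})

test_that("mean RGS to actives behaves as an order-free mean", {
  acts <- lapply(c("c1ccccc1", "Cc1ccccc1"), smiles_to_graph)
  self <- smiles_to_graph("c1ccccc1")
  expect_equal(mean_rgs_to_actives(self, list(self, self)), 1)
  one <- mean_rgs_to_actives(self, acts[2])
  expect_equal(one, rogot_goldberg(morgan_fp(self), morgan_fp(acts[[2]])))
  expect_equal(mean_rgs_to_actives(self, acts),
               mean_rgs_to_actives(self, rev(acts)))
  expect_error(mean_rgs_to_actives(self, list()), "empty")
})

test_that("screening filters, ranks and clamps", {
  model <- trained_lm()
  ds <- model$dataset
  train_smiles <- ds$records$smiles[ds$records$split == "train"]
  actives <- ds$graphs[ds$records$label == "active" &
                       ds$records$split == "train"][1:5]
  test_smiles <- ds$records$smiles[ds$records$split == "test"]

  expect_error(screen(model$params, model$benchmark$protein, character(0),
                      train_smiles, actives))        # empty library

  lib <- c(test_smiles, "not_a_smiles", train_smiles[1:3])
  res <- screen(model$params, model$benchmark$protein, lib, train_smiles,
                actives, top_n = 5)
  expect_equal(res$excluded$unparseable, 1)
  expect_equal(res$excluded$training_set, 3)
  expect_lte(nrow(res$hits), 5)
  expect_true(all(diff(res$hits$probability) <= 0))
  expect_false(any(res$hits$smiles %in% train_smiles))
  expect_true(all(res$hits$mean_rgs >= 0 & res$hits$mean_rgs <= 1))

  # a library containing only training molecules leaves no candidates
  expect_error(screen(model$params, model$benchmark$protein, train_smiles[1:4],
                      train_smiles, actives), "no candidates")
  # top_n larger than the candidate pool returns everything ranked
  res2 <- screen(model$params, model$benchmark$protein, test_smiles[1:3],
                 train_smiles, actives, top_n = 50)
  expect_equal(nrow(res2$hits), 3)
})
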