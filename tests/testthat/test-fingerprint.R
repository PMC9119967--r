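test_that("fingerprints are deterministic, structure-sensitive and order-free", {
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(morgan_fp(g), morgan_fp(g))
  expect_false(identical(morgan_fp(smiles_to_graph("C")),
                         morgan_fp(smiles_to_graph("c1ccccc1"))))
  # canonicalized spelling (different atom order) gives the same bits
  s <- "OC(=O)Cc1ccc(N)cc1"
  can <- canonical_smiles(s)
  expect_false(identical(s, can))
  expect_identical(morgan_fp(smiles_to_graph(s)),
                   morgan_fp(smiles_to_graph(can)))
})

test_that("Rogot-Goldberg similarity matches the closed form", {
  a <- rep(FALSE, 8); a[c(2, 3)] <- TRUE
  b <- rep(FALSE, 8); b[c(3, 4)] <- TRUE
  expect_equal(rogot_goldberg(a, b), 1 / 4 + 5 / 12, tolerance = 1e-4)
  expect_equal(rogot_goldberg(a, a), 1)
  expect_equal(rogot_goldberg(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_error(rogot_goldberg(a, b[1:4]), "mismatch")
})

test_that("RGS decreases as agreement is traded for symmetric difference", {
  set.seed(8)
  x <- runif(64) > 0.5
  y <- x
  vals <- numeric(0)
  flip <- sample(which(x), 5)
  for (i in flip) {
    y[i] <- FALSE                  # common on-bit becomes exclusive
    vals <- c(vals, rogot_goldberg(x, y))
  }
  expect_true(all(diff(c(1, vals)) < 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("Murcko scaffolds keep rings and linkers, drop side chains", {
  sc <- murcko_scaffold(smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O"))
  expect_false(sc$empty)
  expect_equal(length(sc$atoms), 6)                       # benzene core
  expect_true(all(sc$graph$atoms$atomic_num == 6))
  expect_true(all(sc$graph$atoms$aromatic))

  benz <- murcko_scaffold(smiles_to_graph("c1ccccc1"))
  expect_equal(length(benz$atoms), 6)                     # fixed point

  expect_true(murcko_scaffold(smiles_to_graph("CCO"))$empty)

  # scaffold atom counts agree with the reference implementation
  smiles <- c("CC(=O)Oc1ccccc1C(=O)O", "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
              "O=C1CCCCC1CC", "c1ccc2ccccc2c1")
  refs <- rdkit_reference(smiles, "smiles")
  for (i in seq_along(smiles)) {
    expect_equal(length(murcko_scaffold(smiles_to_graph(smiles[i]))$atoms),
                 refs[[i]]$scaffold_n_atoms, info = smiles[i])
  }
})

test_that("scaffold distance vanishes at the scaffold itself", {
  ref <- planet:::scaffold_ref(smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O"))
  expect_equal(scaffold_distance(ref$scaffold$graph, ref), 0)
})

test_that("mu calibration is the maximum over non-empty scaffolds", {
  rings <- lapply(c("c1ccccc1", "c1ccncc1"), smiles_to_graph)
  mu0 <- calibrate_mu(rings)              # molecules equal their scaffolds
  expect_equal(as.numeric(mu0), 0)

  mols <- lapply(c("Cc1ccccc1", "CCCc1ccccc1"), smiles_to_graph)
  d <- vapply(mols, function(m) scaffold_distance(m, m), numeric(1))
  expect_equal(as.numeric(calibrate_mu(mols)), max(d))
  # adding a molecule cannot decrease mu
  expect_gte(as.numeric(calibrate_mu(c(mols, rings[1]))),
             as.numeric(calibrate_mu(mols)))
  # acyclic actives are excluded and reported
  mu <- calibrate_mu(c(mols, list(smiles_to_graph("CCO"))))
  expect_equal(attr(mu, "excluded"), 1L)
  expect_error(calibrate_mu(list(smiles_to_graph("CCO"))), "empty scaffold")
})

test_that("Rogot-Goldberg minimizes the molecule-scaffold distance", {
  bm <- bench_easy()
  graphs <- bm$dataset$graphs[1:50]
  metrics <- list(tanimoto = tanimoto_sim, dice = dice_sim,
                  sokal = sokal_sim, russel = russel_sim,
                  rogot_goldberg = rogot_goldberg)
  dist_mean <- vapply(metrics, function(f) {
    mean(vapply(graphs, function(g) {
      ref <- planet:::scaffold_ref(g)
      1 - f(ref$fp, morgan_fp(g))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(names(which.min(dist_mean)), "rogot_goldberg")
})
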