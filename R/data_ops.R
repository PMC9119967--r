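# Per-target active/decoy datasets: curation (canonical deduplication,
# removal of variably labelled molecules), deterministic stratified
# splitting, virtual screening and similarity diagnostics.

#' Build a target-ligand dataset
#'
#' @param target_id Target identifier.
#' @param smiles Character vector of ligand SMILES.
#' @param label Labels: `"active"`/`"decoy"` (or 1/0).
#' @param build_graphs Featurize all records immediately (default `TRUE`).
#' @return A `tli_dataset`: `records` data frame (smiles, canonical, label,
#'   split), `graphs` (list of `mol_graph` or `NULL`), `target_id`.
#' @export
as_tli_dataset <- function(target_id, smiles, label, build_graphs = TRUE) {
  label <- normalize_labels(label)
  records <- data.frame(smiles = as.character(smiles),
                        canonical = canonical_smiles(smiles),
                        label = label,
                        split = NA_character_,
                        stringsAsFactors = FALSE)
  graphs <- if (build_graphs) lapply(records$smiles, function(s) {
    tryCatch(smiles_to_graph(s), error = function(e) NULL)
  }) else vector("list", nrow(records))
  structure(list(target_id = target_id, records = records, graphs = graphs),
            class = "tli_dataset")
}

normalize_labels <- function(label) {
  if (is.numeric(label)) label <- ifelse(label == 1, "active", "decoy")
  label <- tolower(as.character(label))
  if (!all(label %in% c("active", "decoy")))
    stop("labels must be active/decoy or 1/0", call. = FALSE)
  label
}

# graphs + numeric labels for one side of the split
dataset_part <- function(dataset, part) {
  idx <- which(dataset$records$split == part)
  list(graphs = dataset$graphs[idx],
       labels = as.numeric(dataset$records$label[idx] == "active"),
       index = idx)
}

#' Curate a per-target record set
#'
#' Canonicalizes SMILES and applies the dataset hygiene rules: unparseable
#' records are dropped (counted separately), exact duplicate
#' (molecule, label) records beyond the first are dropped, and any molecule
#' appearing with both labels for the target is removed entirely (all its
#' records). Record conservation holds exactly:
#' `input = output + unparseable + duplicates + variably_labelled_records`.
#'
#' @param dataset A `tli_dataset`, or a data frame with `smiles` and `label`
#'   columns.
#' @param target_id Target id when a data frame is given.
#' @return A curated `tli_dataset` with a `report` attribute-like element:
#'   list with `input_records`, `unparseable_removed`, `duplicates_removed`,
#'   `variably_labeled_molecules`, `variably_labeled_records_removed`,
#'   `output_records`, `removed_fraction`.
#' @export
curate <- function(dataset, target_id = "target") {
  if (is.data.frame(dataset)) {
    dataset <- as_tli_dataset(target_id, dataset$smiles, dataset$label,
                              build_graphs = FALSE)
  }
  rec <- dataset$records
  n_in <- nrow(rec)
  ok <- !is.na(rec$canonical)
  n_unparseable <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  graphs <- dataset$graphs[ok]

  key <- paste(rec$canonical, rec$label, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]; graphs <- graphs[!dup]

  lab_of <- split(rec$label, rec$canonical)
  both <- names(lab_of)[vapply(lab_of, function(x) length(unique(x)) > 1, logical(1))]
  var_rows <- rec$canonical %in% both
  n_var_records <- sum(var_rows)
  rec <- rec[!var_rows, , drop = FALSE]; graphs <- graphs[!var_rows]
  rownames(rec) <- NULL

  out <- dataset
  out$records <- rec
  out$graphs <- graphs
  out$report <- list(
    input_records = n_in,
    unparseable_removed = n_unparseable,
    duplicates_removed = n_dup,
    variably_labeled_molecules = length(both),
    variably_labeled_records_removed = n_var_records,
    output_records = nrow(rec),
    removed_fraction = if (n_in > 0) (n_in - nrow(rec)) / n_in else 0
  )
  out
}

#' Stratified train/test split
#'
#' @param dataset A curated `tli_dataset` with both classes present.
#' @param test_fraction Held-out fraction per class (default 0.10).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return The dataset with `records$split` filled with "train"/"test".
#' @export
split_dataset <- function(dataset, test_fraction = 0.10, seed = 1L) {
  rec <- dataset$records
  set.seed(seed)
  rec$split <- NA_character_
  for (lv in unique(rec$label)) {
    idx <- which(rec$label == lv)
    if (length(idx) < 2)
      stop(sprintf("class '%s' has fewer than 2 records", lv), call. = FALSE)
    n_test <- round(test_fraction * length(idx))
    test <- sample(idx, n_test)
    rec$split[idx] <- "train"
    rec$split[test] <- "test"
  }
  dataset$records <- rec
  dataset
}

#' Mean Rogot-Goldberg similarity to a set of actives
#'
#' @param graph A `mol_graph` (or SMILES string).
#' @param actives List of `mol_graph`s (or SMILES); must be non-empty.
#' @param config An [augmentation_config()] carrying fingerprint parameters.
#' @return Mean pairwise RGS in `[0, 1]`.
#' @export
mean_rgs_to_actives <- function(graph, actives, config = augmentation_config()) {
  if (length(actives) == 0) stop("empty active set", call. = FALSE)
  if (is.character(graph)) graph <- smiles_to_graph(graph)
  fp <- morgan_fp(graph, config$radius, config$nbits)
  sims <- vapply(actives, function(a) {
    if (is.character(a)) a <- smiles_to_graph(a)
    rogot_goldberg(fp, morgan_fp(a, config$radius, config$nbits))
  }, numeric(1))
  mean(sims)
}

#' Virtual screening of a compound library
#'
#' Drops unparseable SMILES and molecules already in the target's training
#' set (canonical-SMILES comparison), scores the remainder with the fused
#' model, and returns the top-scoring hits with their mean Rogot-Goldberg
#' similarity to the training actives.
#'
#' @param params A trained `fusion_params`.
#' @param protein Protein `mol_graph` of the target.
#' @param library_smiles Character vector of candidate SMILES.
#' @param training_smiles SMILES of the molecules used for training (the
#'   exclusion set).
#' @param training_actives List of `mol_graph`s of the training actives (for
#'   the similarity diagnostic).
#' @param top_n Number of hits to return (clamped to the candidate count).
#' @param config Fingerprint parameters.
#' @return A `screening_result`: `hits` data frame (smiles, probability,
#'   mean_rgs, rank) sorted by descending probability, and `excluded` counts.
#' @export
screen <- function(params, protein, library_smiles, training_smiles,
                   training_actives, top_n = 5L,
                   config = augmentation_config()) {
  canon <- canonical_smiles(library_smiles)
  unparseable <- is.na(canon)
  train_canon <- stats::na.omit(canonical_smiles(training_smiles))
  in_train <- !unparseable & canon %in% train_canon
  keep <- !unparseable & !in_train
  if (!any(keep))
    stop("no candidates left after filtering the library", call. = FALSE)
  graphs <- lapply(library_smiles[keep], smiles_to_graph)
  pred <- predict_interaction(graphs, protein, params)
  ord <- order(-pred$probability)
  take <- ord[seq_len(min(top_n, length(ord)))]
  hits <- data.frame(
    smiles = library_smiles[keep][take],
    probability = pred$probability[take],
    mean_rgs = vapply(graphs[take], mean_rgs_to_actives,
                      numeric(1), actives = training_actives, config = config),
    rank = seq_along(take)
  )
  structure(list(hits = hits,
                 excluded = list(unparseable = sum(unparseable),
                                 training_set = sum(in_train))),
            class = "screening_result")
}

#' Read a `smiles,label` CSV
#'
#' @param path CSV file with columns `smiles` and `label`
#'   (`active`/`decoy` or 1/0).
#' @return Data frame with normalized labels.
#' @export
read_smiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("smiles", "label") %in% names(df)))
    stop("CSV must have smiles and label columns", call. = FALSE)
  df$label <- normalize_labels(df$label)
  df
}
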