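# Synthetic desk-scale benchmarks with planted ground truth.
#
# Actives share a fused bicyclic scaffold (naphthalene) decorated with a
# label-determining carboxylate motif plus random small substituents; decoys
# are either property-matched molecules on other scaffolds (easy split) or
# same-scaffold molecules lacking the motif (hard split). Molecules are
# assembled as SMILES strings from ring templates, so the atom indices of
# the planted motif are known exactly and a substructure-matching oracle can
# certify separability.

.ring_templates <- list(
  naphthalene = list(tokens = c("c1", "c", "c", "c2", "c", "c", "c", "c", "c2", "c1"),
                     sub = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 10L)),
  benzene     = list(tokens = c("c1", "c", "c", "c", "c", "c1"), sub = 1:6),
  pyridine    = list(tokens = c("c1", "c", "c", "n", "c", "c1"),
                     sub = c(1L, 2L, 3L, 5L, 6L)),
  cyclohexane = list(tokens = c("C1", "C", "C", "C", "C", "C1"), sub = 1:6)
)

frag_natoms <- function(frag) {
  length(gregexpr("Cl|Br|[BCNOFPSI]", frag)[[1]][gregexpr("Cl|Br|[BCNOFPSI]", frag)[[1]] > 0])
}

# Assemble a substituted ring SMILES. `subs` is a named list mapping template
# position -> substituent fragment. Returns the SMILES plus the atom indices
# contributed by each substituent (atom order = token order, which the
# parser preserves).
assemble_template <- function(template, subs) {
  out <- character(0)
  atom <- 0L
  frag_atoms <- list()
  for (i in seq_along(template$tokens)) {
    out <- c(out, template$tokens[i])
    atom <- atom + 1L
    key <- as.character(i)
    if (!is.null(subs[[key]])) {
      frag <- subs[[key]]
      k <- frag_natoms(frag)
      out <- c(out, "(", frag, ")")
      frag_atoms[[key]] <- atom + seq_len(k)
      atom <- atom + k
    }
  }
  list(smiles = paste(out, collapse = ""), frag_atoms = frag_atoms,
       n_atoms = atom)
}

#' Fixture specification
#'
#' @param scaffold Template name of the actives' shared core (default
#'   `"naphthalene"`, a fused bicyclic ring).
#' @param motif Label-determining substituent fragment (default a
#'   carboxylate-bearing side chain, `"CC(=O)O"`, severable by single-bond
#'   deletion).
#' @param n_actives,n_decoys Class sizes (at least 4 each; default 40).
#' @param hard_split Decoys share the actives' scaffold but lack the motif
#'   (default `FALSE`: decoys come from other scaffolds, matched on
#'   heavy-atom count).
#' @param max_heavy Heavy-atom budget per molecule (default 40).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(scaffold = "naphthalene", motif = "CC(=O)O",
                         n_actives = 40L, n_decoys = 40L, hard_split = FALSE,
                         max_heavy = 40L, seed = 1L) {
  stopifnot(n_actives >= 4, n_decoys >= 4, scaffold %in% names(.ring_templates))
  structure(list(scaffold = scaffold, motif = motif,
                 n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 hard_split = isTRUE(hard_split),
                 max_heavy = as.integer(max_heavy), seed = as.integer(seed)),
            class = "fixture_spec")
}

.small_subs <- c("C", "F", "Cl", "N")              # oxygen-free by design
.bulk_subs <- c("C", "CC", "CCC", "C(C)C", "F", "Cl", "N")

#' Generate a synthetic target-ligand benchmark
#'
#' Produces a per-target active/decoy dataset with known ground truth:
#' every active contains the motif substructure at recorded atom indices; no
#' decoy contains it (decoy substituents carry no oxygen, so a
#' motif-substructure oracle separates the classes perfectly). A toy protein
#' target is emitted as a short random peptide sequence.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `tli_benchmark`: `dataset` (a `tli_dataset` with
#'   graphs), `motif_atoms` (per-record atom indices of the motif, `NULL`
#'   for decoys), `protein_sequence`, `protein` (its `mol_graph`) and
#'   `spec`.
#' @export
generate_benchmark <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  template <- .ring_templates[[spec$scaffold]]
  motif_k <- frag_natoms(spec$motif)

  gen_active <- function() {
    pos <- sample(template$sub, 1)
    extra <- setdiff(template$sub, pos)
    k <- sample(0:2, 1)
    subs <- stats::setNames(list(spec$motif), as.character(pos))
    if (k > 0) {
      at <- sample(extra, k)
      for (p in at) subs[[as.character(p)]] <- sample(.small_subs, 1)
    }
    asm <- assemble_template(template, subs)
    if (asm$n_atoms > spec$max_heavy)
      stop("decoration impossible within the heavy-atom budget", call. = FALSE)
    list(smiles = asm$smiles, motif_atoms = asm$frag_atoms[[as.character(pos)]])
  }

  gen_hard_decoy <- function() {
    k <- sample(1:3, 1)
    at <- sample(template$sub, k)
    subs <- stats::setNames(as.list(sample(.small_subs, k, replace = TRUE)),
                            as.character(at))
    assemble_template(template, subs)$smiles
  }

  gen_easy_decoy <- function(target_atoms) {
    tname <- sample(setdiff(names(.ring_templates), spec$scaffold), 1)
    tpl <- .ring_templates[[tname]]
    subs <- list()
    count <- length(tpl$tokens)
    for (p in sample(tpl$sub)) {
      if (count >= target_atoms) break
      frag <- sample(.bulk_subs, 1)
      if (count + frag_natoms(frag) > spec$max_heavy) next
      subs[[as.character(p)]] <- frag
      count <- count + frag_natoms(frag)
    }
    assemble_template(tpl, subs)$smiles
  }

  uniq <- character(0)
  actives <- list()
  while (length(actives) < spec$n_actives) {
    cand <- gen_active()
    key <- canonical_smiles(cand$smiles)
    if (is.na(key) || key %in% uniq) next
    uniq <- c(uniq, key)
    actives[[length(actives) + 1]] <- cand
  }
  active_sizes <- vapply(actives, function(a) {
    sum(gregexpr("Cl|Br|[bcnospBCNOFPSI]", a$smiles)[[1]] > 0)
  }, numeric(1))
  decoys <- character(0)
  while (length(decoys) < spec$n_decoys) {
    s <- if (spec$hard_split) gen_hard_decoy()
         else gen_easy_decoy(sample(active_sizes, 1))
    key <- canonical_smiles(s)
    if (is.na(key) || key %in% uniq) next
    uniq <- c(uniq, key)
    decoys <- c(decoys, s)
  }

  smiles <- c(vapply(actives, `[[`, character(1), "smiles"), decoys)
  labels <- c(rep("active", spec$n_actives), rep("decoy", spec$n_decoys))
  dataset <- as_tli_dataset(paste0("synthetic_", spec$scaffold), smiles, labels)
  motif_atoms <- c(lapply(actives, `[[`, "motif_atoms"),
                   vector("list", spec$n_decoys))

  protein_sequence <- paste(sample(names(.aa_side_chains), sample(8:30, 1),
                                   replace = TRUE), collapse = "")
  structure(list(dataset = dataset, motif_atoms = motif_atoms,
                 protein_sequence = protein_sequence,
                 protein = fasta_to_graph(protein_sequence),
                 spec = spec),
            class = "tli_benchmark")
}

#' Plant duplicates and label conflicts into a record set
#'
#' Corrupts a clean record set with a known number of exact duplicates and
#' active/decoy conflicts, returning the expected curation report so the
#' curation rules can be asserted exactly.
#'
#' @param records Data frame with `smiles` and `label` columns (each
#'   molecule appearing once).
#' @param n_dups Number of exact duplicate records to append.
#' @param n_conflicts Number of molecules to which a flipped-label record is
#'   appended.
#' @param seed Integer seed.
#' @return List with `records` (corrupted, shuffled) and `expected` counts
#'   (`duplicates`, `variable_molecules`, `variable_records`).
#' @export
generate_duplicates_fixture <- function(records, n_dups, n_conflicts, seed = 1L) {
  set.seed(seed)
  stopifnot(n_dups >= 0, n_conflicts >= 0,
            n_dups + n_conflicts <= nrow(records))
  idx <- sample(nrow(records), n_dups + n_conflicts)
  dup_idx <- idx[seq_len(n_dups)]
  conf_idx <- idx[setdiff(seq_along(idx), seq_len(n_dups))]
  extra <- records[c(dup_idx, conf_idx), , drop = FALSE]
  if (n_conflicts > 0) {
    flip <- extra$label[n_dups + seq_len(n_conflicts)]
    extra$label[n_dups + seq_len(n_conflicts)] <-
      ifelse(flip == "active", "decoy", "active")
  }
  out <- rbind(records, extra)
  out <- out[sample(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       expected = list(duplicates = n_dups,
                       variable_molecules = n_conflicts,
                       variable_records = 2L * n_conflicts))
}
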