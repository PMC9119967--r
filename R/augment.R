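# Gradient-based, scaffold-bounded adversarial molecule augmentation.
#
# Each chemical bond carries a binary coefficient of value 1 multiplying its
# feature rows; multiplying by 1 leaves every prediction bit-identical, but
# the coefficient's gradient after backpropagating the training loss ranks
# how much each bond contributes to the prediction. The bond with the most
# negative gradient is deleted, provided the bond-deleted structure stays
# within the scaffold-distance threshold mu; otherwise the next candidate is
# tried, and the molecule is skipped when none qualifies.

#' Per-bond loss gradients
#'
#' Instruments every directed edge with a unit coefficient, backpropagates
#' the binary cross-entropy loss at `label`, and sums each bond's two
#' directed-edge coefficient gradients.
#'
#' @param ligand A `mol_graph`.
#' @param params A `fusion_params`.
#' @param label Loss label (1: the molecule's active label).
#' @param protein Optional protein `mol_graph`; when `NULL` the ligand-only
#'   head (the augmented-LM training path) is used.
#' @return Data frame with one row per chemical bond: `bond`, `a1`, `a2`,
#'   `gradient`.
#' @export
edge_gradients <- function(ligand, params, label = 1, protein = NULL) {
  res <- edge_gradients_batch(list(ligand), params, labels = label,
                              protein = protein)
  res[[1]]
}

# Batched version: one tape for a whole set of molecules.
edge_gradients_batch <- function(ligands, params, labels, protein = NULL) {
  batch <- graph_batch(ligands)
  tape <- tape_new()
  out <- if (is.null(protein)) {
    ligand_only_forward_tape(tape, batch, params, with_edge_coeff = TRUE)
  } else {
    fused_forward_tape(tape, batch, params, protein, with_edge_coeff = TRUE)
  }
  loss <- op_bce_logits(tape, out$logit, labels)
  grads <- tape_backward(tape, loss)
  gc_ <- if (is.null(out$lig$edge_coeff)) NULL else grads[[out$lig$edge_coeff$id]]
  lapply(seq_along(ligands), function(i) {
    g <- ligands[[i]]
    m <- nrow(g$bonds)
    grad <- numeric(m)
    if (m > 0 && !is.null(gc_)) {
      sel <- batch$graph_of_edge == i
      grad <- as.numeric(rowsum(as.numeric(gc_)[sel], group = batch$bond_of_edge[sel]))
    }
    data.frame(bond = seq_len(m), a1 = g$bonds$a1, a2 = g$bonds$a2,
               gradient = grad)
  })
}

#' Select and delete one bond under the scaffold bound
#'
#' Iterates bonds with negative gradient in ascending gradient order (most
#' negative first, ties by lower bond index), deletes the bond (both directed
#' edges) and accepts the first candidate whose distance to the original
#' molecule's Bemis-Murcko scaffold does not exceed `mu`. Returns `NULL` when
#' no candidate qualifies (no negative gradient, empty scaffold, or every
#' deletion violates the bound).
#'
#' @param ligand A `mol_graph`.
#' @param gradients Data frame from [edge_gradients()].
#' @param ref A `scaffold_ref` of the original molecule (or the molecule
#'   itself).
#' @param mu Scaffold-distance threshold.
#' @param config An [augmentation_config()] (fingerprint parameters).
#' @return An `augmentation_result` (original, augmented graph, deleted bond
#'   atom pair, gradient, distance) or `NULL`.
#' @export
select_and_delete <- function(ligand, gradients, ref, mu,
                              config = augmentation_config()) {
  if (inherits(ref, "mol_graph")) ref <- scaffold_ref(ref, config)
  if (ref$empty) return(NULL)
  cand <- gradients[gradients$gradient < 0, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(cand$gradient, cand$bond), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    bond <- cand$bond[i]
    aug <- delete_bond(ligand, bond)
    d <- scaffold_distance(aug, ref)
    if (d <= mu) {
      return(structure(list(original = ligand, augmented = aug,
                            deleted_bond = c(cand$a1[i], cand$a2[i]),
                            bond = bond, gradient = cand$gradient[i],
                            distance = d),
                       class = "augmentation_result"))
    }
  }
  NULL
}

#' Augment a batch of active molecules
#'
#' For each active, computes per-bond gradients under the current model,
#' attempts one scaffold-bounded deletion, and appends every success (still
#' labelled active) to the batch alongside the originals.
#'
#' @param ligands List of `mol_graph`s (the batch's actives).
#' @param params A `fusion_params` (current model state).
#' @param mu Calibrated scaffold-distance threshold.
#' @param config An [augmentation_config()].
#' @param protein Optional protein graph (when augmenting a fused model).
#' @return List with `augmented` (list of `augmentation_result`s) and
#'   `skipped` (count of actives yielding no augmentation).
#' @export
augment_batch <- function(ligands, params, mu, config = augmentation_config(),
                          protein = NULL) {
  if (length(ligands) == 0) return(list(augmented = list(), skipped = 0L))
  grads <- edge_gradients_batch(ligands, params, labels = rep(1, length(ligands)),
                                protein = protein)
  out <- vector("list", length(ligands))
  for (i in seq_along(ligands)) {
    ref <- scaffold_ref(ligands[[i]], config)
    out[i] <- list(select_and_delete(ligands[[i]], grads[[i]], ref, mu, config))
  }
  ok <- !vapply(out, is.null, logical(1))
  list(augmented = out[ok], skipped = sum(!ok))
}
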