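# Two-module fused model: ligand GCN + protein GCN, a scalar gate on the
# protein embedding (zero-initialised so joint training starts from the
# ligand-only behaviour), a merge layer over the concatenated embeddings and
# a single-logit classifier. A separate ligand-only classifier head serves
# the stages trained without protein information.

#' Initialize fused model parameters
#'
#' @param lig_config,prot_config [gcn_config()]s for the ligand and protein
#'   modules (protein defaults to the ligand config).
#' @param alpha_init Protein-gate initialization: `"zero"` (default; joint
#'   training starts exactly at the ligand-only behaviour) or `"random"`.
#' @return A `fusion_params` list with elements `lm`, `pm` (module
#'   parameters), `alpha`, merge and classifier weights, and the ligand-only
#'   head.
#' @export
init_fusion_params <- function(lig_config, prot_config = lig_config,
                               alpha_init = c("zero", "random")) {
  alpha_init <- match.arg(alpha_init)
  h <- lig_config$hidden_dim
  stopifnot(prot_config$hidden_dim == h)
  structure(list(
    lm = init_module_params(lig_config),
    pm = init_module_params(prot_config),
    alpha = if (alpha_init == "zero") 0 else stats::rnorm(1),
    merge_w = glorot(2 * h, h), merge_b = rep(0, h),
    clf_w = glorot(h, 1), clf_b = 0,
    lig_clf_w = glorot(h, 1), lig_clf_b = 0,
    lig_config = lig_config, prot_config = prot_config
  ), class = "fusion_params")
}

# Fused forward on a tape. `protein_emb_override` replaces the protein-module
# output (used by the constant-vector ablation); `protein` may then be NULL.
fused_forward_tape <- function(tape, lig_batch, params, protein = NULL,
                               training = FALSE, with_edge_coeff = FALSE,
                               registry = NULL, protein_emb_override = NULL,
                               prot_batch = NULL) {
  lig <- gcn_forward_tape(tape, lig_batch, params$lm, params$lig_config,
                          training = training, prefix = "lm/",
                          with_edge_coeff = with_edge_coeff,
                          registry = registry)
  if (!is.null(protein_emb_override)) {
    prot_pooled <- ad_const(tape, protein_emb_override)
  } else {
    if (is.null(prot_batch)) prot_batch <- graph_batch(protein)
    prot <- gcn_forward_tape(tape, prot_batch, params$pm, params$prot_config,
                             training = training, prefix = "pm/",
                             registry = registry)
    prot_pooled <- prot$pooled
  }
  # one protein row broadcast across the ligand batch
  if (nrow(prot_pooled$v) == 1 && lig_batch$n_graphs > 1) {
    prot_pooled <- op_gather(tape, prot_pooled, rep(1L, lig_batch$n_graphs))
  }
  bindf <- param_binder(tape, "fusion/", registry)
  alpha <- bindf(params$alpha, "alpha")
  gated <- op_scale(tape, prot_pooled, alpha)
  cat_ <- op_concat_cols(tape, lig$pooled, gated)
  merged <- op_relu(tape, op_add_vec(tape,
    op_matmul(tape, cat_, bindf(params$merge_w, "merge_w")),
    bindf(params$merge_b, "merge_b")))
  logit <- op_add_vec(tape, op_matmul(tape, merged, bindf(params$clf_w, "clf_w")),
                      bindf(params$clf_b, "clf_b"))
  list(logit = logit, lig = lig)
}

ligand_only_forward_tape <- function(tape, lig_batch, params, training = FALSE,
                                     with_edge_coeff = FALSE, registry = NULL) {
  lig <- gcn_forward_tape(tape, lig_batch, params$lm, params$lig_config,
                          training = training, prefix = "lm/",
                          with_edge_coeff = with_edge_coeff, registry = registry)
  bindf <- param_binder(tape, "fusion/", registry)
  logit <- op_add_vec(tape,
                      op_matmul(tape, lig$pooled, bindf(params$lig_clf_w, "lig_clf_w")),
                      bindf(params$lig_clf_b, "lig_clf_b"))
  list(logit = logit, lig = lig)
}

as_prediction <- function(logit) {
  logit <- as.numeric(logit)
  data.frame(logit = logit, probability = 1 / (1 + exp(-logit)))
}

#' Predict a target-ligand interaction probability
#'
#' Runs the fused model in evaluation mode: ligand and protein graphs are
#' embedded by their modules, the protein embedding is scaled by the gate
#' `alpha`, both are concatenated, merged and classified to a logistic
#' probability. With `alpha = 0` the output is exactly independent of the
#' protein graph.
#'
#' @param ligand A `mol_graph` or list of them.
#' @param protein A `mol_graph` for the target protein.
#' @param params A `fusion_params`.
#' @return Data frame with columns `logit` and `probability` (one row per
#'   ligand).
#' @export
predict_interaction <- function(ligand, protein, params) {
  tape <- tape_new()
  out <- fused_forward_tape(tape, graph_batch(ligand), params, protein)
  as_prediction(out$logit$v)
}

#' Ligand-only prediction
#'
#' The ligand embedding is passed directly through the ligand-only
#' classification head; no protein information is used.
#'
#' @inheritParams predict_interaction
#' @return Data frame with columns `logit` and `probability`.
#' @export
predict_ligand_only <- function(ligand, params) {
  tape <- tape_new()
  out <- ligand_only_forward_tape(tape, graph_batch(ligand), params)
  as_prediction(out$logit$v)
}

#' Constant-protein ablation
#'
#' Identical to [predict_interaction()] but the protein module's output is
#' replaced by a constant all-ones vector (the gate still applies), so the
#' prediction is independent of any protein graph.
#'
#' @inheritParams predict_interaction
#' @return Data frame with columns `logit` and `probability`.
#' @export
constant_protein_ablation <- function(ligand, params) {
  tape <- tape_new()
  batch <- graph_batch(ligand)
  ones <- matrix(1, batch$n_graphs, params$lig_config$hidden_dim)
  out <- fused_forward_tape(tape, batch, params, protein_emb_override = ones)
  as_prediction(out$logit$v)
}

#' Gradient saliency map over ligand atoms
#'
#' Backpropagates the binary cross-entropy loss at the supplied label to the
#' ligand's node input embeddings and sums the gradient over embedding
#' coordinates, giving one score per heavy atom. Atoms are ranked ascending:
#' the most negative gradient (largest contribution to decreasing the loss)
#' ranks first.
#'
#' @param ligand A `mol_graph`.
#' @param protein Optional protein `mol_graph`; when `NULL` the ligand-only
#'   head is used.
#' @param params A `fusion_params`.
#' @param label Interaction label the loss is evaluated at (1 for actives).
#' @return List of class `saliency_map`: `score` (per atom) and `ranking`
#'   (atom indices, most important first).
#' @export
saliency <- function(ligand, protein = NULL, params, label = 1) {
  tape <- tape_new()
  batch <- graph_batch(ligand)
  out <- if (is.null(protein)) {
    ligand_only_forward_tape(tape, batch, params)
  } else {
    fused_forward_tape(tape, batch, params, protein)
  }
  loss <- op_bce_logits(tape, out$logit, label)
  grads <- tape_backward(tape, loss)
  gx <- grads[[out$lig$x0$id]]
  score <- rowSums(gx)
  structure(list(score = score, ranking = order(score)), class = "saliency_map")
}
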