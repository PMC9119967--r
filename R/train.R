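# Multi-stage training curriculum: (1) ligand module alone, (2) protein
# module jointly with the stage-1 ligand module through the zero-initialised
# gate, (3) a fresh ligand module trained with per-batch adversarial
# augmentation, (4) fusion of the stage-2 protein module with the stage-3
# ligand module, training only the merge and classification layers.
# Optimizer: Adam; model selection: best validation AP per stage.

#' Stage configuration
#'
#' Defaults follow the published curriculum: LM (300 epochs, LR 5e-3, no
#' augmentation), LM_PM (20 epochs, LR 5e-4), LM_A (300 epochs, LR 5e-4,
#' augmentation on), FUSION (20 epochs, LR 5e-5, merge + classifier only).
#'
#' @param stage One of `"LM"`, `"LM_PM"`, `"LM_A"`, `"FUSION"`.
#' @param epochs,learning_rate Optional overrides of the stage defaults.
#' @param augmentation Optional override of the stage's augmentation flag.
#' @return A `stage_config` list with a `trainable` path-prefix regex.
#' @export
stage_config <- function(stage = c("LM", "LM_PM", "LM_A", "FUSION"),
                         epochs = NULL, learning_rate = NULL,
                         augmentation = NULL) {
  stage <- match.arg(stage)
  defaults <- list(
    LM     = list(epochs = 300L, lr = 5e-3, aug = FALSE,
                  trainable = "^(lm/|fusion/lig_clf)"),
    LM_PM  = list(epochs = 20L,  lr = 5e-4, aug = FALSE,
                  trainable = "^(lm/|pm/|fusion/(alpha|merge|clf))"),
    LM_A   = list(epochs = 300L, lr = 5e-4, aug = TRUE,
                  trainable = "^(lm/|fusion/lig_clf)"),
    FUSION = list(epochs = 20L,  lr = 5e-5, aug = FALSE,
                  trainable = "^fusion/(alpha|merge|clf)")
  )[[stage]]
  structure(list(stage = stage,
                 epochs = as.integer(epochs %||% defaults$epochs),
                 learning_rate = learning_rate %||% defaults$lr,
                 augmentation = augmentation %||% defaults$aug,
                 trainable = defaults$trainable),
            class = "stage_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Desk-scale curriculum
#'
#' The four stages with epoch counts small enough for a laptop CPU
#' (40/15/40/15), for use with [desk_config()] modules. The fusion stage's
#' learning rate is raised to 1e-3: the published 5e-5 is calibrated to
#' full-scale data volumes (thousands of optimizer steps over 20 epochs),
#' while a desk-scale dataset yields only tens of steps, far too few for
#' the merge head to re-adapt to the stage-3 backbone at that rate.
#'
#' @return List of [stage_config()]s.
#' @export
desk_curriculum <- function() {
  list(stage_config("LM", epochs = 40L),
       stage_config("LM_PM", epochs = 15L),
       stage_config("LM_A", epochs = 40L),
       stage_config("FUSION", epochs = 15L, learning_rate = 1e-3))
}

## ---- parameter plumbing ----------------------------------------------------

param_path_get <- function(params, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (parts[1] == "fusion") return(params[[parts[2]]])
  x <- params[[parts[1]]]
  for (p in parts[-1]) {
    x <- if (grepl("^[0-9]+$", p)) x[[as.integer(p)]] else x[[p]]
  }
  x
}

param_path_set <- function(params, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (parts[1] == "fusion") { params[[parts[2]]] <- value; return(params) }
  set_rec <- function(x, parts, value) {
    key <- if (grepl("^[0-9]+$", parts[1])) as.integer(parts[1]) else parts[1]
    if (length(parts) == 1) { x[[key]] <- value; return(x) }
    x[[key]] <- set_rec(x[[key]], parts[-1], value)
    x
  }
  params[[parts[1]]] <- set_rec(params[[parts[1]]], parts[-1], value)
  params
}

collect_grads <- function(registry, grads) {
  out <- list()
  for (path in ls(registry)) {
    g <- grads[[registry[[path]]]]
    if (!is.null(g)) out[[path]] <- g
  }
  out
}

adam_update <- function(params, grad_list, lr, state, trainable_regex,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- (state$t %||% 0L) + 1L
  t <- state$t
  for (path in names(grad_list)) {
    if (!grepl(trainable_regex, path)) next
    val <- param_path_get(params, path)
    g <- grad_list[[path]]
    if (is.matrix(val)) g <- matrix(as.numeric(g), nrow(val), ncol(val))
    else g <- as.numeric(g)
    st <- state[[path]] %||% list(m = 0 * g, v = 0 * g)
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    state[[path]] <- st
    params <- param_path_set(params, path, val - lr * mhat / (sqrt(vhat) + eps))
  }
  params
}

# Deep snapshot of parameters including the mutable normalization state.
snapshot_params <- function(params) {
  params$lm$bn_state <- list2env(as.list(params$lm$bn_state),
                                 parent = emptyenv())
  params$pm$bn_state <- list2env(as.list(params$pm$bn_state),
                                 parent = emptyenv())
  params
}

eval_ap <- function(params, graphs, labels, protein, head) {
  pred <- switch(head,
                 ligand = predict_ligand_only(graphs, params),
                 fused = predict_interaction(graphs, protein, params))
  average_precision(pred$probability, labels)
}

## ---- one stage -------------------------------------------------------------

# Train one stage. `data` is list(graphs, labels) for training;
# `val` the same for validation. Returns list(params, history, best_val_ap).
train_stage <- function(params, cfg, data, val, protein,
                        batch_size = 64L, aug_config = augmentation_config(),
                        mu = NULL, verbose = FALSE) {
  head <- if (cfg$stage %in% c("LM", "LM_A")) "ligand" else "fused"
  opt <- new.env(parent = emptyenv())
  n <- length(data$graphs)
  if (cfg$stage == "LM_A" && is.null(mu)) {
    mu <- calibrate_mu(data$graphs[data$labels == 1], aug_config)
  }
  best <- list(ap = eval_ap(params, val$graphs, val$labels, protein, head),
               params = snapshot_params(params))
  history <- data.frame(epoch = 0L, loss = NA_real_, val_ap = best$ap)
  aug_log <- list()
  if (cfg$epochs > 0 && n > 0) {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        graphs <- data$graphs[idx]
        labels <- data$labels[idx]
        if (cfg$augmentation) {
          actives <- graphs[labels == 1]
          if (length(actives) > 0) {
            aug <- augment_batch(actives, params, mu, aug_config)
            if (length(aug$augmented) > 0) {
              graphs <- c(graphs, lapply(aug$augmented, `[[`, "augmented"))
              labels <- c(labels, rep(1, length(aug$augmented)))
              aug_log <- c(aug_log, aug$augmented)
            }
          }
        }
        tape <- tape_new()
        registry <- new.env(parent = emptyenv())
        batch <- graph_batch(graphs)
        out <- if (head == "ligand") {
          ligand_only_forward_tape(tape, batch, params, training = TRUE,
                                   registry = registry)
        } else {
          fused_forward_tape(tape, batch, params, protein, training = TRUE,
                             registry = registry)
        }
        loss <- op_bce_logits(tape, out$logit, labels)
        grads <- tape_backward(tape, loss)
        params <- adam_update(params, collect_grads(registry, grads),
                              cfg$learning_rate, opt, cfg$trainable)
        losses <- c(losses, loss$v[1, 1])
      }
      val_ap <- eval_ap(params, val$graphs, val$labels, protein, head)
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = mean(losses),
                                  val_ap = val_ap))
      if (val_ap > best$ap + 1e-12) {
        best <- list(ap = val_ap, params = snapshot_params(params))
      }
      if (verbose) message(sprintf("[%s] epoch %d loss %.4f val AP %.4f",
                                   cfg$stage, epoch, mean(losses), val_ap))
    }
  }
  list(params = best$params, final_params = params, history = history,
       best_val_ap = best$ap, mu = mu, aug_log = aug_log)
}

## ---- full curriculum -------------------------------------------------------

#' Run the multi-stage training curriculum
#'
#' Executes the four stages on a curated dataset with a train/validation
#' split: (1) a ligand module on original molecules, (2) a randomly
#' initialised protein module trained jointly with the stage-1 ligand module
#' (protein gate starting at zero), (3) a fresh ligand module trained with
#' per-batch adversarial augmentation, and (4) fusion of the stage-2 protein
#' module with the stage-3 ligand module, training merge and classifier
#' layers with frozen backbones. Within each stage the checkpoint with the
#' best validation AP is kept.
#'
#' @param dataset A `tli_dataset` with graphs and a `train`/`test` split
#'   (see [as_tli_dataset()], [split_dataset()]); validation uses the test
#'   part of the split.
#' @param protein Protein `mol_graph` of the target.
#' @param stages List of [stage_config()]s (default [desk_curriculum()]).
#' @param config Module [gcn_config()] (default [desk_config()]).
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation.
#' @param batch_size Mini-batch size (default 64).
#' @param aug_config Fingerprint/threshold settings for stage LM_A.
#' @param verbose Print per-epoch progress.
#' @return List of class `curriculum_result`: `params` (final
#'   `fusion_params`), `report` (per-stage and final validation APs, mu, seed)
#'   and `history` (per-stage training curves).
#' @export
run_curriculum <- function(dataset, protein, stages = desk_curriculum(),
                           config = desk_config(), seed = 1L,
                           batch_size = 64L,
                           aug_config = augmentation_config(),
                           verbose = FALSE) {
  set.seed(seed)
  tr <- dataset_part(dataset, "train")
  va <- dataset_part(dataset, "test")
  if (length(unique(tr$labels)) < 2 || length(unique(va$labels)) < 2)
    stop("train/validation splits must contain both classes", call. = FALSE)
  stage_of <- function(nm) {
    i <- which(vapply(stages, function(s) s$stage, character(1)) == nm)
    if (length(i) == 0) NULL else stages[[i[1]]]
  }
  history <- list(); report <- list(seed = seed)

  model1 <- init_fusion_params(config, alpha_init = "zero")
  s1 <- train_stage(model1, stage_of("LM") %||% stage_config("LM"),
                    tr, va, protein, batch_size, verbose = verbose)
  history$LM <- s1$history; report$LM <- s1$best_val_ap

  s2cfg <- stage_of("LM_PM") %||% stage_config("LM_PM")
  s2 <- train_stage(s1$params, s2cfg, tr, va, protein, batch_size,
                    verbose = verbose)
  history$LM_PM <- s2$history; report$LM_PM <- s2$best_val_ap

  model3 <- init_fusion_params(config, alpha_init = "zero")
  s3cfg <- stage_of("LM_A") %||% stage_config("LM_A")
  s3 <- train_stage(model3, s3cfg, tr, va, protein, batch_size,
                    aug_config = aug_config, verbose = verbose)
  history$LM_A <- s3$history; report$LM_A <- s3$best_val_ap; report$mu <- s3$mu

  fused <- s2$params
  fused$lm <- s3$params$lm
  s4cfg <- stage_of("FUSION") %||% stage_config("FUSION")
  s4 <- train_stage(fused, s4cfg, tr, va, protein, batch_size,
                    verbose = verbose)
  history$FUSION <- s4$history; report$FUSION <- s4$best_val_ap
  report$final_ap <- s4$best_val_ap

  structure(list(params = s4$params, report = report, history = history),
            class = "curriculum_result")
}

#' Stratified cross-validation of the curriculum
#'
#' Assigns stratified folds within the training split, then runs the full
#' curriculum once per fold with the held-out fold as validation.
#'
#' @param dataset A `tli_dataset` (the train part of its split is folded).
#' @param protein Protein `mol_graph`.
#' @param folds Number of folds (default 4).
#' @param seed Integer seed (fold assignment and each run).
#' @param ... Passed to [run_curriculum()].
#' @return List with `reports` (one per fold), `fold_ap` and `mean_ap`.
#' @export
cross_validate <- function(dataset, protein, folds = 4L, seed = 1L, ...) {
  tr_idx <- which(dataset$records$split == "train")
  labels <- dataset$records$label[tr_idx]
  fold_id <- stratified_folds(labels, folds, seed)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    sub <- dataset
    sub$records <- dataset$records[tr_idx, , drop = FALSE]
    sub$graphs <- dataset$graphs[tr_idx]
    sub$records$split <- ifelse(fold_id == f, "test", "train")
    if (length(unique(sub$records$label[sub$records$split == "test"])) < 2)
      stop(sprintf("fold %d lacks a class", f), call. = FALSE)
    reports[[f]] <- run_curriculum(sub, protein, seed = seed + f, ...)$report
  }
  fold_ap <- vapply(reports, function(r) r$final_ap, numeric(1))
  list(reports = reports, fold_ap = fold_ap, mean_ap = mean(fold_ap))
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}
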