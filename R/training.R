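# End-to-end pretraining. The decoder never sees ground-truth coordinates:
# it receives residue tokens only, and the atom-37 template coordinates
# enter solely as supervision targets, masked to the occupied slots of the
# true residue identities. The encoder is equivariant by construction, so
# no rotation augmentation is used. By default the desk-scale protocol
# freezes the encoder at its seeded initialization and caches embeddings
# (invariance and locality are architectural, and the decoder carries the
# reconstruction task); set train_encoder = TRUE to propagate gradients
# through the tensor-product encoder as well.

#' Pretraining configuration
#'
#' @param encoder an [encoder_config()].
#' @param decoder a [decoder_config()].
#' @param weights a [loss_weights()].
#' @param lr Adam learning rate (peak value under the cosine schedule).
#' @param lr_schedule "constant" or "cosine" (decay to lr/20 over the
#'   run).
#' @param steps optimization steps (>= 1).
#' @param batch_size structures per step (default: full batch).
#' @param max_residues length cap; longer chains are cropped with a
#'   warning (512, the evaluation ceiling).
#' @param train_encoder propagate gradients into the encoder.
#' @param fape_unclamped_every if > 0, every k-th step computes the FAPE
#'   term without its distance clamp. The clamp caps per-atom errors and
#'   so silences gradients for far-misplaced atoms; mixing periodic
#'   unclamped steps (the protocol used with this loss family) restores a
#'   global signal while keeping the robustness of clamping. 0 disables.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param seed integer seed (model init and batch order).
#' @param checkpoint_every steps between checkpoint snapshots kept in the
#'   training log (0 disables).
#' @return a `pretrain_config` list.
#' @export
pretrain_config <- function(encoder = encoder_config(),
                            decoder = decoder_config(),
                            weights = loss_weights(),
                            lr = 1e-3, lr_schedule = c("constant", "cosine"),
                            steps = 2000L, batch_size = NULL,
                            max_residues = 512L, train_encoder = FALSE,
                            fape_unclamped_every = 0L,
                            grad_clip = 1, seed = 1L,
                            checkpoint_every = 0L) {
  stopifnot(steps >= 1L)
  lr_schedule <- match.arg(lr_schedule)
  structure(list(encoder = encoder, decoder = decoder, weights = weights,
                 lr = lr, lr_schedule = lr_schedule,
                 steps = as.integer(steps),
                 batch_size = batch_size,
                 max_residues = as.integer(max_residues),
                 train_encoder = isTRUE(train_encoder),
                 fape_unclamped_every = as.integer(fape_unclamped_every),
                 grad_clip = grad_clip, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "pretrain_config")
}

# ---- Adam ----------------------------------------------------------------

# Adam over the flattened parameter vector (single vectorized update)
adam_init <- function(params) {
  n <- sum(vapply(params, length, integer(1)))
  list(m = numeric(n), v = numeric(n), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

flatten_like <- function(grads, params) {
  unlist(lapply(names(params), function(nm) {
    g <- grads[[nm]]
    if (is.null(g)) numeric(length(params[[nm]])) else as.numeric(g)
  }), use.names = FALSE)
}

adam_step <- function(params, grads, state, lr, grad_clip = 0) {
  g <- flatten_like(grads, params)
  if (grad_clip > 0) {
    gn <- sqrt(sum(g * g))
    if (is.finite(gn) && gn > grad_clip) g <- g * (grad_clip / gn)
  }
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g * g
  upd <- lr * (state$m / (1 - b1^state$t)) /
    (sqrt(state$v / (1 - b2^state$t)) + state$eps)
  off <- 0L
  for (nm in names(params)) {
    len <- length(params[[nm]])
    params[[nm]] <- params[[nm]] - upd[off + seq_len(len)]
    off <- off + len
  }
  list(params = params, state = state)
}

# ---- per-structure supervision constants ---------------------------------

prep_example <- function(structure, energy, config) {
  n0 <- structure$n_residues
  if (n0 > config$max_residues) {
    warning("cropping structure from ", n0, " to ", config$max_residues,
            " residues")
    structure <- crop_structure(structure, config$max_residues)
    if (!is.null(energy)) {
      energy <- energy_table(
        energy$values[seq_len(config$max_residues),
                      seq_len(config$max_residues), , drop = FALSE])
    }
  }
  if (is.null(energy)) energy <- surrogate_pair_energies(structure)
  n <- structure$n_residues
  fl <- flatten_coords(structure$coords, structure$atom_mask)
  frames <- build_frames(structure$coords, structure$atom_mask)
  list(
    structure = structure,
    n = n,
    labels = match(structure$residue_types, AA3),
    keep = fl$keep,
    lddt_pairs = lddt_pairs(fl$x[fl$keep, , drop = FALSE],
                            fl$residue[fl$keep]),
    true_local = true_local_coords(fl$x, fl$keep, frames, n),
    energy_flat = matrix(energy$values, n * n, 3L),
    energy_mask = matrix(as.numeric(energy$pair_mask), n * n, 3L),
    graph = NULL, z = NULL
  )
}

crop_structure <- function(structure, n) {
  all_atom_structure(structure$residue_types[seq_len(n)],
                     structure$coords[seq_len(n), , , drop = FALSE],
                     structure$atom_mask[seq_len(n), , drop = FALSE],
                     structure$chain_labels[seq_len(n)])
}

# loss nodes for one decoded example
example_loss_nodes <- function(dec_out, ex, weights, fape_clamp = 10) {
  n <- ex$n
  pf <- frames_node(dec_out$coords, n)
  fape <- fape_node(dec_out$coords, pf, ex$true_local, ex$keep, n,
                    clamp = fape_clamp)
  pred_kept <- td_rows(dec_out$coords, which(ex$keep))
  lddt <- smooth_lddt_node(pred_kept, ex$lddt_pairs)
  ce <- seq_ce_node(dec_out$seq_logits, ex$labels)
  mse <- energy_mse_node(dec_out$energy, ex$energy_flat, ex$energy_mask)
  coord <- td_add(td_smul(lddt, weights$alpha), td_smul(fape, weights$beta))
  total <- td_add(td_add(td_smul(coord, weights$w_coord),
                         td_smul(ce, weights$w_seq)),
                  td_smul(mse, weights$w_energy))
  list(total = total, lddt = lddt, fape = fape, ce = ce, mse = mse)
}

schedule_lr <- function(config, step) {
  if (identical(config$lr_schedule, "cosine")) {
    lr_min <- config$lr / 20
    lr_min + 0.5 * (config$lr - lr_min) *
      (1 + cos(pi * (step - 1) / max(config$steps - 1, 1)))
  } else {
    config$lr
  }
}

# one optimization step over a batch of prepped examples (internal)
step_internal <- function(model, examples, config, opt, lr = config$lr,
                          step = opt$t + 1L) {
  weights <- config$weights
  train_enc <- config$train_encoder
  k <- config$fape_unclamped_every
  fape_clamp <- if (!is.null(k) && k > 0L && step %% k == 0L) Inf else 10
  comp <- c(total = 0, lddt = 0, fape = 0, ce = 0, mse = 0)
  grad_sum <- NULL
  for (ex in examples) {
    td_reset()
    enc_pn <- wrap_params(model$enc_params, trainable = train_enc)
    dec_pn <- wrap_params(model$dec_params, trainable = TRUE)
    if (train_enc) {
      pooled <- encoder_forward(ex$graph, enc_pn, config$encoder)
      z_node <- pooled$residue
    } else {
      z_node <- td_const(ex$z)
    }
    dec_out <- decoder_forward(z_node, dec_pn, config$decoder,
                               ex$structure$residue_types)
    ln <- example_loss_nodes(dec_out, ex, weights, fape_clamp)
    if (!is.finite(td_value(ln$total)[1])) {
      stop("non-finite loss on example with ", ex$n, " residues")
    }
    td_backward(ln$total)
    g <- lapply(dec_pn, td_grad)
    if (train_enc) {
      ge <- lapply(enc_pn, td_grad)
      names(ge) <- paste0("enc.", names(ge))
      g <- c(g, ge)
    }
    g <- lapply(g, function(x) if (is.null(x)) NULL else x)
    grad_sum <- if (is.null(grad_sum)) g else
      mapply(function(a, b) {
        if (is.null(a)) b else if (is.null(b)) a else a + b
      }, grad_sum, g, SIMPLIFY = FALSE)
    for (nm in names(comp)) comp[nm] <- comp[nm] + td_value(ln[[nm]])[1]
  }
  td_reset()
  nb <- length(examples)
  comp <- comp / nb
  grads <- lapply(grad_sum, function(g) if (is.null(g)) NULL else g / nb)
  all_params <- model$dec_params
  if (train_enc) {
    enc_named <- model$enc_params
    names(enc_named) <- paste0("enc.", names(enc_named))
    all_params <- c(all_params, enc_named)
  }
  upd <- adam_step(all_params, grads, opt, lr, config$grad_clip)
  dec_names <- names(model$dec_params)
  model$dec_params <- upd$params[dec_names]
  if (train_enc) {
    enc_names <- paste0("enc.", names(model$enc_params))
    ep <- upd$params[enc_names]
    names(ep) <- names(model$enc_params)
    model$enc_params <- ep
  }
  list(model = model, opt = upd$state, components = comp)
}

#' Initialize an encoder + decoder model
#'
#' @param encoder an [encoder_config()].
#' @param decoder a [decoder_config()].
#' @return list with `enc_params`, `dec_params` and the two configs.
#' @export
slae_model <- function(encoder = encoder_config(),
                       decoder = decoder_config()) {
  list(encoder = encoder, decoder = decoder,
       enc_params = init_encoder_params(encoder),
       dec_params = init_decoder_params(decoder))
}

#' One pretraining step
#'
#' Runs a single optimization step of the combined objective on a batch
#' of structures and returns the loss breakdown. Deterministic given
#' identical model/optimizer state and batch.
#'
#' @param model a [slae_model()] (or checkpoint model field).
#' @param batch list of [all_atom_structure()]; or prepped examples.
#' @param config a [pretrain_config()].
#' @param opt optimizer state (default: fresh Adam).
#' @param energies optional list of [energy_table()] aligned with batch.
#' @return list(model, opt, components) where components holds
#'   (total, lddt, fape, ce, mse); `total` recombines the parts via the
#'   combined-objective arithmetic.
#' @export
pretrain_step <- function(model, batch, config = pretrain_config(),
                          opt = NULL, energies = NULL) {
  if (length(batch) == 0L) stop("empty batch")
  examples <- lapply(seq_along(batch), function(i) {
    b <- batch[[i]]
    if (!is.null(b$lddt_pairs)) return(b)  # already prepped
    ex <- prep_example(b, if (is.null(energies)) NULL else energies[[i]],
                       config)
    ex <- attach_inputs(ex, model, config)
    ex
  })
  if (is.null(opt)) {
    opt <- adam_init(step_params(model, config))
  }
  step_internal(model, examples, config, opt)
}

attach_inputs <- function(ex, model, config) {
  if (config$train_encoder) {
    ex$graph <- build_local_graph(ex$structure,
                                  cutoff = config$encoder$cutoff,
                                  n_basis = config$encoder$n_basis,
                                  lmax = config$encoder$lmax,
                                  node_vocab = config$encoder$node_vocab)
  } else {
    ex$z <- encode(ex$structure, config$encoder,
                   params = model$enc_params)$z
  }
  ex
}

step_params <- function(model, config) {
  all_params <- model$dec_params
  if (config$train_encoder) {
    enc_named <- model$enc_params
    names(enc_named) <- paste0("enc.", names(enc_named))
    all_params <- c(all_params, enc_named)
  }
  all_params
}

#' Pretrain on a set of structures
#'
#' Full training loop: caches energy labels (computed once per
#' structure), freezes or trains the encoder per the config, optimizes
#' the combined objective with Adam, and logs the per-step loss
#' breakdown.
#'
#' @param dataset list of [all_atom_structure()], or a directory of PDB
#'   files.
#' @param config a [pretrain_config()].
#' @param energies optional list of [energy_table()] aligned with the
#'   dataset (default: surrogate labels).
#' @param verbose print progress every 100 steps.
#' @return a checkpoint: list with `model`, `config`, `log` (data.frame
#'   step/total/lddt/fape/ce/mse), `opt`, `step`.
#' @export
pretrain <- function(dataset, config = pretrain_config(), energies = NULL,
                     verbose = FALSE) {
  if (is.character(dataset)) {
    paths <- list.files(dataset, pattern = "\\.pdb$", full.names = TRUE)
    dataset <- lapply(paths, read_pdb)
  }
  if (length(dataset) == 0L) stop("empty dataset")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed)
  model <- slae_model(config$encoder, config$decoder)
  examples <- lapply(seq_along(dataset), function(i) {
    ex <- prep_example(dataset[[i]],
                       if (is.null(energies)) NULL else energies[[i]],
                       config)
    attach_inputs(ex, model, config)
  })
  opt <- adam_init(step_params(model, config))
  bs <- if (is.null(config$batch_size)) length(examples) else
    min(config$batch_size, length(examples))
  log <- matrix(0, config$steps, 6L)
  colnames(log) <- c("step", "total", "lddt", "fape", "ce", "mse")
  for (step in seq_len(config$steps)) {
    idx <- if (bs == length(examples)) seq_along(examples) else
      ((step - 1L) * bs + seq_len(bs) - 1L) %% length(examples) + 1L
    res <- step_internal(model, examples[idx], config, opt,
                         lr = schedule_lr(config, step))
    model <- res$model; opt <- res$opt
    log[step, ] <- c(step, res$components)
    if (verbose && (step %% 100L == 0L || step == 1L)) {
      message(sprintf("step %d  total %.4f  lddt %.4f fape %.4f ce %.4f mse %.4f",
                      step, res$components["total"], res$components["lddt"],
                      res$components["fape"], res$components["ce"],
                      res$components["mse"]))
    }
  }
  list(model = model, config = config,
       log = as.data.frame(log), opt = opt, step = config$steps)
}

#' Resume pretraining from a checkpoint
#'
#' @param checkpoint a [pretrain()] result (or loaded checkpoint).
#' @param dataset as in [pretrain()].
#' @param extra_steps additional steps to run.
#' @param energies optional energy tables.
#' @return updated checkpoint with extended log.
#' @export
pretrain_resume <- function(checkpoint, dataset, extra_steps,
                            energies = NULL) {
  config <- checkpoint$config
  model <- checkpoint$model
  examples <- lapply(seq_along(dataset), function(i) {
    ex <- prep_example(dataset[[i]],
                       if (is.null(energies)) NULL else energies[[i]],
                       config)
    attach_inputs(ex, model, config)
  })
  opt <- checkpoint$opt
  log <- matrix(0, extra_steps, 6L)
  colnames(log) <- c("step", "total", "lddt", "fape", "ce", "mse")
  for (k in seq_len(extra_steps)) {
    res <- step_internal(model, examples, config, opt)
    model <- res$model; opt <- res$opt
    log[k, ] <- c(checkpoint$step + k, res$components)
  }
  checkpoint$model <- model; checkpoint$opt <- opt
  checkpoint$step <- checkpoint$step + extra_steps
  checkpoint$log <- rbind(checkpoint$log, as.data.frame(log))
  checkpoint
}

#' Save / load a checkpoint
#'
#' Self-describing archive: model parameters with both configs embedded.
#' @param checkpoint a [pretrain()] result.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!all(c("model", "config") %in% names(ck))) {
    stop("not a valid checkpoint file: ", path)
  }
  ck
}

#' Evaluate reconstruction quality
#'
#' Encodes and decodes every structure and reports sequence recovery
#' (fraction of residues whose argmax logit matches the truth, in %) and
#' all-atom RMSD (Kabsch-superposed, over the occupied slots of the true
#' identities), with cumulative length bins at <128 and <512 residues.
#'
#' @param checkpoint a [pretrain()] result (or a bare [slae_model()]).
#' @param dataset list of [all_atom_structure()].
#' @return list with `per_structure` (data.frame), `seq_accuracy` (%),
#'   `mean_rmsd` (A) and `bins` (data.frame).
#' @export
evaluate_reconstruction <- function(checkpoint, dataset) {
  model <- if (!is.null(checkpoint$model)) checkpoint$model else checkpoint
  enc_cfg <- model$encoder; dec_cfg <- model$decoder
  rows <- lapply(dataset, function(s) {
    z <- encode(s, enc_cfg, params = model$enc_params)
    out <- decode(z, dec_cfg, params = model$dec_params,
                  residue_types = s$residue_types)
    pred_idx <- max.col(out$seq_logits, ties.method = "first")
    acc <- mean(pred_idx == match(s$residue_types, AA3))
    keep <- as.vector(s$atom_mask)
    xa <- matrix(s$coords, ncol = 3L)[keep, , drop = FALSE]
    xb <- matrix(out$coords_hat, ncol = 3L)[keep, , drop = FALSE]
    data.frame(n_residues = s$n_residues, seq_accuracy = 100 * acc,
               rmsd = rmsd_points(xa, xb))
  })
  per <- do.call(rbind, rows)
  bins <- do.call(rbind, lapply(c(128L, 512L), function(cap) {
    sel <- per$n_residues < cap
    data.frame(bin = paste0("<", cap), n_structures = sum(sel),
               seq_accuracy = if (any(sel)) mean(per$seq_accuracy[sel]) else NA,
               mean_rmsd = if (any(sel)) mean(per$rmsd[sel]) else NA)
  }))
  list(per_structure = per,
       seq_accuracy = mean(per$seq_accuracy),
       mean_rmsd = mean(per$rmsd),
       bins = bins)
}
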