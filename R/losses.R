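# Pretraining objectives. Every loss is implemented on autodiff tape
# nodes (so the training loop differentiates through them) and exposed
# with a plain numeric wrapper for direct evaluation. Masked atoms and
# pairs are excluded from every mean, never zero-filled.
#
# Combined objective:
#   L = w_coord * (alpha * SmoothLDDT + beta * FAPE)
#       + w_seq * CrossEntropy + w_energy * MSE

#' Loss weights of the combined objective
#'
#' @param w_coord,w_seq,w_energy non-negative task weights.
#' @param alpha,beta non-negative mix of the two coordinate losses.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(w_coord = 1, w_seq = 1, w_energy = 0.1,
                         alpha = 1, beta = 1) {
  vals <- c(w_coord, w_seq, w_energy, alpha, beta)
  if (any(vals < 0)) stop("loss weights must be non-negative")
  structure(list(w_coord = w_coord, w_seq = w_seq, w_energy = w_energy,
                 alpha = alpha, beta = beta), class = "loss_weights")
}

# flatten an n x 37 x 3 array to the (n*37) x 3 slot-major layout used on
# tape, plus the matching mask vector
flatten_coords <- function(coords, mask) {
  n <- dim(coords)[1]
  list(x = matrix(coords, n * 37L, 3L), keep = as.vector(mask),
       residue = rep(seq_len(n), times = 37L))
}

# smooth lDDT internals shared by wrapper and tape path -------------------

lddt_pairs <- function(true_x, residue_index, inclusion_radius = 15) {
  m <- nrow(true_x)
  if (m < 2L) stop("smooth lDDT needs at least 2 atoms after masking")
  d <- as.matrix(stats::dist(true_x))
  ut <- upper.tri(d)
  ok <- ut & d < inclusion_radius
  if (!is.null(residue_index)) {
    same <- outer(residue_index, residue_index, "==")
    ok <- ok & !same
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no atom pairs inside the inclusion radius")
  list(i = idx[, 1], j = idx[, 2], d_true = d[ok])
}

smooth_lddt_node <- function(pred_node, pairs) {
  di <- td_rows(pred_node, pairs$i)
  dj <- td_rows(pred_node, pairs$j)
  dp <- td_rownorm(td_sub(di, dj))
  delta <- td_abs(td_sub(dp, td_const(matrix(pairs$d_true, ncol = 1L))))
  # sigmoid agreement at each threshold, normalized so zero distance
  # error scores exactly 1 (sigma(tau - delta) / sigma(tau))
  score <- NULL
  for (tau in c(0.5, 1, 2, 4)) {
    s <- td_smul(td_sigmoid(td_sadd(td_smul(delta, -1), tau)),
                 1 / stats::plogis(tau))
    score <- if (is.null(score)) s else td_add(score, s)
  }
  td_sadd(td_smul(td_mean(score), -0.25), 1)   # 1 - mean score
}

#' Smooth lDDT loss
#'
#' One minus the smooth local distance difference test score: over all
#' atom pairs of the true structure within the inclusion radius (15 A,
#' different residues), the score averages sigmoid agreements of the
#' pairwise-distance error at thresholds 0.5, 1, 2 and 4 A. The loss is
#' in [0, 1], superposition-free, and 0 for predictions that preserve all
#' included distances.
#'
#' @param pred,true n x 37 x 3 coordinate arrays.
#' @param mask n x 37 logical occupancy (shared by both structures).
#' @param residue_index optional override of the per-atom residue index
#'   used to exclude same-residue pairs; pass NULL to keep all pairs.
#' @param inclusion_radius pair inclusion radius on the true structure, A.
#' @return scalar loss.
#' @export
smooth_lddt_loss <- function(pred, true, mask,
                             residue_index = "from_mask",
                             inclusion_radius = 15) {
  fp <- flatten_coords(pred, mask); ft <- flatten_coords(true, mask)
  ri <- if (identical(residue_index, "from_mask")) ft$residue[ft$keep]
        else residue_index
  pairs <- lddt_pairs(ft$x[ft$keep, , drop = FALSE], ri, inclusion_radius)
  td_reset()
  v <- td_value(smooth_lddt_node(td_const(fp$x[fp$keep, , drop = FALSE]),
                                 pairs))[1]
  td_reset()
  v
}

# backbone frames ----------------------------------------------------------

frames_node <- function(coords_node, n) {
  # rows 1..n are N, rows n+1..2n CA, 2n+1..3n C (slot-major layout)
  Nn <- td_rows(coords_node, seq_len(n))
  CA <- td_rows(coords_node, n + seq_len(n))
  Cc <- td_rows(coords_node, 2L * n + seq_len(n))
  v1 <- td_sub(Cc, CA)
  e1 <- td_bmul_col(v1, td_inv_col(td_rownorm(v1)))
  u <- td_sub(Nn, CA)
  proj <- td_rowsums(td_mul(u, e1))
  v2 <- td_sub(u, td_bmul_col(e1, proj))
  e2 <- td_bmul_col(v2, td_inv_col(td_rownorm(v2)))
  e3 <- td_cross(e1, e2)
  list(origin = CA, e1 = e1, e2 = e2, e3 = e3)
}

#' Reciprocal of a positive column vector (tape op)
#' @param x td_node (n x 1), entries > 0.
#' @export
td_inv_col <- function(x) {
  xv <- x$value
  new_node(1 / xv, list(x), function(g) list(-g / (xv * xv)))
}

#' Backbone frames from N, CA, C coordinates
#'
#' Gram-Schmidt frame per residue: origin at CA, first axis along CA->C,
#' second axis the CA->N component orthogonal to it, third their cross
#' product. Rotations are proper and orthonormal.
#'
#' @param coords n x 37 x 3 array.
#' @param mask n x 37 logical; N, CA and C must be present for every
#'   residue.
#' @return list with `origin` (n x 3) and `rotation` (n x 3 x 3, rows of
#'   each rotation are the frame axes).
#' @export
build_frames <- function(coords, mask) {
  n <- dim(coords)[1]
  if (!all(mask[, 1:3])) stop("every residue needs N, CA and C for frames")
  fl <- flatten_coords(coords, mask)
  # degenerate check
  Nx <- fl$x[seq_len(n), , drop = FALSE]
  CAx <- fl$x[n + seq_len(n), , drop = FALSE]
  Cx <- fl$x[2L * n + seq_len(n), , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- sqrt(rowSums(cr(Cx - CAx, Nx - CAx)^2))
  if (any(area < 1e-6)) stop("collinear N, CA, C: degenerate frame")
  td_reset()
  fr <- frames_node(td_const(fl$x), n)
  rot <- array(0, dim = c(n, 3L, 3L))
  rot[, 1L, ] <- td_value(fr$e1)
  rot[, 2L, ] <- td_value(fr$e2)
  rot[, 3L, ] <- td_value(fr$e3)
  out <- list(origin = td_value(fr$origin), rotation = rot)
  td_reset()
  out
}

fape_node <- function(pred_node, pred_frames, true_local, keep, n,
                      clamp = 10, scale = 10) {
  # local coordinates of every kept atom in every frame, per axis
  parts <- vector("list", 3L)
  axes <- list(pred_frames$e1, pred_frames$e2, pred_frames$e3)
  kept <- td_rows(pred_node, which(keep))
  for (k in 1:3) {
    A <- td_matmul(axes[[k]], td_t(kept))                    # n x m
    b <- td_rowsums(td_mul(axes[[k]], pred_frames$origin))   # n x 1
    loc <- td_bsub_col(A, b)
    parts[[k]] <- td_square(td_sub(loc, td_const(true_local[[k]])))
  }
  d <- td_safe_sqrt(td_add(td_add(parts[[1]], parts[[2]]), parts[[3]]))
  td_smul(td_mean(td_pmin_const(d, clamp)), 1 / scale)
}

true_local_coords <- function(true_x, keep, frames, n) {
  xm <- true_x[keep, , drop = FALSE]
  lapply(1:3, function(k) {
    E <- frames$rotation[, k, ]
    E %*% t(xm) - rowSums(E * frames$origin)
  })
}

#' Frame-aligned point error (FAPE)
#'
#' Mean over (residue frame f, occupied atom a) of the clamped distance
#' between the prediction and the truth expressed in f's local
#' coordinates, divided by `scale`. Invariant to independent global rigid
#' motions of the prediction and of the truth.
#'
#' @param pred,true n x 37 x 3 coordinate arrays.
#' @param mask n x 37 logical occupancy.
#' @param clamp clamp distance in Angstrom (default 10).
#' @param scale normalization in Angstrom (default 10).
#' @return scalar loss.
#' @export
fape_loss <- function(pred, true, mask, clamp = 10, scale = 10) {
  n <- dim(pred)[1]
  true_frames <- build_frames(true, mask)
  fl_t <- flatten_coords(true, mask)
  tl <- true_local_coords(fl_t$x, fl_t$keep, true_frames, n)
  fl_p <- flatten_coords(pred, mask)
  td_reset()
  pf <- frames_node(td_const(fl_p$x), n)
  v <- td_value(fape_node(td_const(fl_p$x), pf, tl, fl_p$keep, n,
                          clamp, scale))[1]
  td_reset()
  v
}

# sequence cross-entropy ----------------------------------------------------

seq_ce_node <- function(logits_node, labels_idx) {
  n <- length(labels_idx)
  e <- td_exp(td_sub(logits_node,
                     td_const(matrix(apply(td_value(logits_node), 1, max),
                                     n, 20))))
  lse <- td_log(td_rowsums(e))
  onehot <- diag(20L)[labels_idx, , drop = FALSE]
  picked <- td_rowsums(td_mul(logits_node, td_const(onehot)))
  shift <- td_const(matrix(apply(td_value(logits_node), 1, max), ncol = 1))
  td_smul(td_mean(td_sub(lse, td_sub(picked, shift))), 1)
}

#' Sequence cross-entropy
#'
#' Mean categorical cross-entropy (nats per residue) of the predicted
#' 20-class logits against the true residue types.
#'
#' @param seq_logits n x 20 matrix.
#' @param labels three-letter codes (length n) or integer indices into
#'   [AA3].
#' @return scalar loss in nats.
#' @export
sequence_ce <- function(seq_logits, labels) {
  idx <- if (is.character(labels)) match(toupper(labels), AA3) else
    as.integer(labels)
  if (anyNA(idx)) stop("invalid residue labels")
  if (length(idx) != nrow(seq_logits)) {
    stop("label length does not match logits")
  }
  td_reset()
  v <- td_value(seq_ce_node(td_const(seq_logits), idx))[1]
  td_reset()
  v
}

# energy regression ----------------------------------------------------------

energy_mse_node <- function(energy_node, true_flat, mask_flat) {
  diff <- td_mul(td_sub(energy_node, td_const(true_flat)),
                 td_const(mask_flat))
  td_smul(td_sum(td_square(diff)), 1 / sum(mask_flat))
}

#' Energy regression loss
#'
#' Mean squared error over the masked residue pairs and the three energy
#' channels (H-bond, electrostatics, solvation).
#'
#' @param energy_hat,energy_true n x n x 3 arrays.
#' @param pair_mask n x n logical; defaults to all off-diagonal pairs.
#' @return scalar loss in squared surrogate-energy units.
#' @export
energy_mse <- function(energy_hat, energy_true, pair_mask = NULL) {
  if (!all(dim(energy_hat) == dim(energy_true))) {
    stop("energy table shapes differ")
  }
  n <- dim(energy_hat)[1]
  if (is.null(pair_mask)) pair_mask <- !diag(n)
  mflat <- matrix(as.numeric(pair_mask), n * n, 3L)
  td_reset()
  v <- td_value(energy_mse_node(
    td_const(matrix(energy_hat, n * n, 3L)),
    matrix(energy_true, n * n, 3L), mflat))[1]
  td_reset()
  v
}

#' Combined pretraining loss
#'
#' Exactly the stated weighted sum:
#' `w_coord * (alpha*lddt + beta*fape) + w_seq*ce + w_energy*mse`.
#'
#' @param components named list or vector with lddt, fape, ce, mse.
#' @param weights a [loss_weights()].
#' @return scalar total.
#' @export
total_loss <- function(components, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  cm <- as.list(components)
  if (!all(is.finite(unlist(cm[c("lddt", "fape", "ce", "mse")])))) {
    stop("non-finite loss component")
  }
  weights$w_coord * (weights$alpha * cm$lddt + weights$beta * cm$fape) +
    weights$w_seq * cm$ce + weights$w_energy * cm$mse
}
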