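toy_structure <- function(pts, atoms = c("N", "CA", "C", "O")) {
  coords <- array(0, dim = c(1, 37, 3))
  mask <- matrix(FALSE, 1, 37)
  slots <- slot_index("ALA", atoms)
  for (k in seq_along(atoms)) {
    coords[1, slots[k], ] <- pts[k, ]
    mask[1, slots[k]] <- TRUE
  }
  list(coords = coords, mask = mask)
}

test_that("smooth lDDT is zero for identical and rigidly moved predictions", {
  s <- test_peptide("ACDEFGHIKL", "helix")
  expect_lt(smooth_lddt_loss(s$coords, s$coords, s$atom_mask), 1e-10)
  for (seed in 1:10) {
    rt <- random_rigid_motion(seed)
    moved <- transform_structure(s, rt$rotation, rt$translation)
    expect_lt(smooth_lddt_loss(moved$coords, s$coords, s$atom_mask), 1e-8)
  }
})

test_that("smooth lDDT matches explicit per-pair arithmetic on a 3-atom toy", {
  # three atoms across three residues so every pair is included
  pts <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  mk <- function(p) {
    coords <- array(0, dim = c(3, 37, 3))
    mask <- matrix(FALSE, 3, 37)
    for (i in 1:3) { coords[i, 2, ] <- p[i, ]; mask[i, 2] <- TRUE }
    list(coords = coords, mask = mask)
  }
  true <- mk(pts)
  pred_pts <- pts; pred_pts[2, 1] <- 4  # perturbs pairs (1,2) and (2,3)
  pred <- mk(pred_pts)
  got <- smooth_lddt_loss(pred$coords, true$coords, true$mask)

  # independent arithmetic: per pair, mean over thresholds of the
  # normalized sigmoid agreement
  d_true <- c(dist(pts))
  d_pred <- c(dist(pred_pts))
  delta <- abs(d_pred - d_true)
  taus <- c(0.5, 1, 2, 4)
  per_pair <- vapply(delta, function(dl) {
    mean(plogis(taus - dl) / plogis(taus))
  }, numeric(1))
  expect_equal(got, 1 - mean(per_pair), tolerance = 1e-6)
})

test_that("backbone frames are orthonormal, right-handed and rotate with the structure", {
  s <- test_peptide("ACDEFG", "strand")
  fr <- build_frames(s$coords, s$atom_mask)
  for (i in seq_len(s$n_residues)) {
    R <- fr$rotation[i, , ]
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-5)
    expect_equal(det(R), 1, tolerance = 1e-5)
  }
  rt <- random_rigid_motion(23)
  fr2 <- build_frames(transform_structure(s, rt$rotation,
                                          rt$translation)$coords,
                      s$atom_mask)
  for (i in seq_len(s$n_residues)) {
    expect_equal(fr2$rotation[i, , ],
                 fr$rotation[i, , ] %*% t(rt$rotation), tolerance = 1e-9)
  }
  # missing N -> error
  bad_mask <- s$atom_mask; bad_mask[2, 1] <- FALSE
  expect_error(build_frames(s$coords, bad_mask), "N, CA and C")
  # collinear backbone -> degenerate
  toy <- toy_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)))
  expect_error(build_frames(toy$coords, toy$mask), "degenerate|collinear")
})

test_that("FAPE is zero under identity and rigid motions of the prediction", {
  s <- test_peptide("ACDEFGHIKL", "helix")
  expect_equal(fape_loss(s$coords, s$coords, s$atom_mask), 0)
  for (seed in 1:10) {
    rt <- random_rigid_motion(100 + seed)
    moved <- transform_structure(s, rt$rotation, rt$translation)
    expect_lt(fape_loss(moved$coords, s$coords, s$atom_mask), 1e-9)
  }
})

test_that("FAPE matches manual arithmetic on a one-residue toy", {
  # one residue, frame from N/CA/C; O displaced by 0.5 A
  pts <- rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.4, 0), c(3.2, 1.4, 0))
  true <- toy_structure(pts)
  pred_pts <- pts
  pred_pts[4, ] <- pts[4, ] + c(0, 0, 0.5)
  pred <- toy_structure(pred_pts)
  got <- fape_loss(pred$coords, true$coords, true$mask,
                   clamp = 10, scale = 10)
  # frames of pred and true share N/CA/C, so three atoms contribute 0 and
  # O contributes 0.5; mean over the 1x4 frame-atom grid, divided by 10
  expect_equal(got, (0.5 / 4) / 10, tolerance = 1e-9)
})

test_that("sequence cross-entropy matches closed forms and hand arithmetic", {
  expect_lt(sequence_ce(matrix(c(30, rep(0, 19)), 1, 20, byrow = TRUE),
                        "ALA"), 1e-3)
  expect_equal(sequence_ce(matrix(0, 5, 20), rep("GLY", 5)), log(20),
               tolerance = 1e-12)
  set.seed(2)
  lg <- matrix(rnorm(40), 2, 20)
  labels <- c("CYS", "TRP")
  idx <- match(labels, AA3)
  byhand <- -mean(vapply(1:2, function(i) {
    lg[i, idx[i]] - log(sum(exp(lg[i, ])))
  }, numeric(1)))
  expect_equal(sequence_ce(lg, labels), byhand, tolerance = 1e-9)
  expect_error(sequence_ce(lg, "ALA"), "length")
})

test_that("energy MSE matches closed forms and a naive loop", {
  E <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  expect_equal(energy_mse(E, E), 0)
  expect_equal(energy_mse(E + 0.3, E), 0.09, tolerance = 1e-12)
  set.seed(4)
  A <- array(rnorm(27), c(3, 3, 3)); B <- array(rnorm(27), c(3, 3, 3))
  acc <- 0; cnt <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    if (i == j) next
    acc <- acc + (A[i, j, k] - B[i, j, k])^2; cnt <- cnt + 1
  }
  expect_equal(energy_mse(A, B), acc / cnt, tolerance = 1e-12)
  expect_error(energy_mse(A, array(0, c(2, 2, 3))), "shape")
})

test_that("the combined loss is exactly the stated weighted sum", {
  expect_equal(total_loss(list(lddt = 0, fape = 0, ce = 0, mse = 0)), 0)
  expect_equal(total_loss(list(lddt = 0.2, fape = 0.1, ce = 1.0, mse = 0.5),
                          loss_weights(1, 1, 0.1, 1, 1)), 1.35)
  w0 <- loss_weights(w_coord = 2, w_seq = 0, w_energy = 0,
                     alpha = 0.7, beta = 0.3)
  expect_equal(total_loss(list(lddt = 0.5, fape = 0.4, ce = 9, mse = 9), w0),
               2 * (0.7 * 0.5 + 0.3 * 0.4))
  expect_error(loss_weights(w_coord = -1), "non-negative")
})

test_that("loss gradients w.r.t. predicted quantities are finite and correct", {
  s <- test_peptide("ACDE", "helix")
  fl <- slae:::flatten_coords(s$coords, s$atom_mask)
  kept <- fl$x[fl$keep, , drop = FALSE]
  pairs <- slae:::lddt_pairs(kept, fl$residue[fl$keep])
  pert <- kept + matrix(rnorm(length(kept), sd = 0.3), nrow(kept))
  expect_grad_matches(function(n) {
    slae:::smooth_lddt_node(n[[1]], pairs)
  }, list(pert), tol = 1e-5)

  n <- s$n_residues
  frames <- build_frames(s$coords, s$atom_mask)
  tl <- slae:::true_local_coords(fl$x, fl$keep, frames, n)
  full_pert <- fl$x + matrix(rnorm(length(fl$x), sd = 0.2), nrow(fl$x))
  expect_grad_matches(function(nd) {
    pf <- slae:::frames_node(nd[[1]], n)
    slae:::fape_node(nd[[1]], pf, tl, fl$keep, n)
  }, list(full_pert), tol = 1e-4)

  set.seed(9)
  lg <- matrix(rnorm(3 * 20), 3)
  expect_grad_matches(function(nd) {
    slae:::seq_ce_node(nd[[1]], c(1L, 5L, 18L))
  }, list(lg), tol = 1e-6)
})
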