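tiny_cfg <- function(steps = 5L, train_encoder = FALSE, ...) {
  pretrain_config(
    encoder = encoder_config(n_layers = 1L, scalar_dim = 16L,
                             n_channels = 4L, lmax = 1L, n_basis = 4L,
                             cutoff = 6, residue_dim = 32L, seed = 2L),
    decoder = decoder_config(model_dim = 32L, n_layers = 1L, n_heads = 2L,
                             mlp_ratio = 2L, pair_hidden = 8L,
                             token_dim = 32L, seed = 3L),
    steps = steps, lr = 2e-3, train_encoder = train_encoder, ...)
}

tiny_data <- function() {
  list(build_ideal_peptide("ACDEFGHI", "helix", seed = 1L),
       build_ideal_peptide("KLMNPQST", "strand", seed = 2L))
}

test_that("a pretraining step is deterministic and reports a recombining breakdown", {
  cfg <- tiny_cfg()
  data <- tiny_data()
  model <- slae_model(cfg$encoder, cfg$decoder)
  r1 <- pretrain_step(model, data, cfg)
  r2 <- pretrain_step(model, data, cfg)
  expect_identical(r1$components, r2$components)
  # components recombine to the total via the combined-objective formula
  w <- cfg$weights
  expect_equal(unname(r1$components["total"]),
               total_loss(as.list(r1$components[c("lddt", "fape", "ce",
                                                  "mse")]), w),
               tolerance = 1e-9)
})

test_that("zero energy weight keeps the mse reported but out of the total", {
  cfg <- tiny_cfg()
  cfg$weights <- loss_weights(w_coord = 1, w_seq = 1, w_energy = 0)
  data <- tiny_data()
  model <- slae_model(cfg$encoder, cfg$decoder)
  r <- pretrain_step(model, data, cfg)
  expect_gt(unname(r$components["mse"]), 0)
  expect_equal(unname(r$components["total"]),
               unname(r$components["lddt"] + r$components["fape"] +
                        r$components["ce"]),
               tolerance = 1e-9)
})

test_that("training reduces the loss, and resumed runs continue the trajectory", {
  cfg <- tiny_cfg(steps = 40L)
  data <- tiny_data()
  ck <- pretrain(data, cfg)
  expect_lt(ck$log$total[40], ck$log$total[1])
  # straight 40 steps == 25 steps + resume 15 (same seeds, full batch)
  cfg25 <- tiny_cfg(steps = 25L)
  ck25 <- pretrain(data, cfg25)
  ck40 <- pretrain_resume(ck25, data, 15L)
  expect_equal(ck40$log$total[40], ck$log$total[40], tolerance = 1e-8)
})

test_that("joint end-to-end training (gradients through the encoder) reduces the loss", {
  cfg <- tiny_cfg(steps = 25L, train_encoder = TRUE)
  data <- list(build_ideal_peptide("ACDEFG", "helix", seed = 1L))
  ck <- pretrain(data, cfg)
  expect_lt(ck$log$total[25], ck$log$total[1])
  # encoder parameters actually moved
  init <- init_encoder_params(cfg$encoder)
  moved <- max(abs(ck$model$enc_params$W_init - init$W_init))
  expect_gt(moved, 0)
})

test_that("checkpoints round-trip through disk", {
  cfg <- tiny_cfg(steps = 3L)
  ck <- pretrain(tiny_data(), cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  back <- load_checkpoint(f)
  expect_identical(back$model$dec_params, ck$model$dec_params)
  expect_error(load_checkpoint({
    g <- withr::local_tempfile(fileext = ".rds"); saveRDS(1:3, g); g
  }), "checkpoint")
})

test_that("evaluation matches an independent tally and sits near chance untrained", {
  cfg <- tiny_cfg()
  data <- tiny_data()
  model <- slae_model(cfg$encoder, cfg$decoder)
  ev <- evaluate_reconstruction(model, data)
  # independent tally on the first structure
  s <- data[[1]]
  z <- encode(s, cfg$encoder, params = model$enc_params)
  out <- decode(z, cfg$decoder, params = model$dec_params)
  tally <- 0
  for (i in seq_len(s$n_residues)) {
    pred <- which.max(out$seq_logits[i, ])
    if (AA3[pred] == s$residue_types[i]) tally <- tally + 1
  }
  expect_equal(ev$per_structure$seq_accuracy[1],
               100 * tally / s$n_residues, tolerance = 1e-9)
  # untrained decoder: near-chance sequence recovery (5% for 20 classes)
  expect_lt(ev$seq_accuracy, 30)
  # every short structure lands in both cumulative bins
  expect_equal(ev$bins$n_structures, c(2L, 2L))
  expect_equal(ev$bins$mean_rmsd[1], ev$bins$mean_rmsd[2])
})

test_that("over-long chains are cropped with a warning", {
  cfg <- tiny_cfg()
  cfg$max_residues <- 6L
  s <- build_ideal_peptide("ACDEFGHIKL", "helix", seed = 1L)
  expect_warning(ex <- slae:::prep_example(s, NULL, cfg), "cropping")
  expect_equal(ex$n, 6L)
})
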