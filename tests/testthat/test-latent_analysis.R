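test_that("interpolation hits both endpoints exactly and spaces t evenly", {
  set.seed(1)
  zA <- matrix(rnorm(6 * 16), 6); zB <- matrix(rnorm(6 * 16), 6)
  path <- interpolate(zA, zB, steps = 11L)
  expect_identical(path$frames[[1]], zA)
  expect_identical(path$frames[[11]], zB)
  expect_equal(path$t, seq(0, 1, length.out = 11))
  # midpoint arithmetic
  z0 <- matrix(0, 2, 4); z2 <- matrix(2, 2, 4)
  mid <- interpolate(z0, z2, steps = 3L)$frames[[2]]
  expect_equal(mid, matrix(1, 2, 4))
  # default is 50 frames
  expect_equal(length(interpolate(zA, zB)$frames), 50L)
  expect_error(interpolate(zA, zB[, 1:8]), "differ")
  expect_error(interpolate(zA, zB, steps = 1L), "steps")
})

test_that("codebooks are deterministic; K = M subsampling returns the inputs", {
  set.seed(2)
  emb <- matrix(rnorm(30 * 8), 30)
  cb1 <- build_codebook(emb, 8L, seed = 3L)
  cb2 <- build_codebook(emb, 8L, seed = 3L)
  expect_identical(cb1$centroids, cb2$centroids)
  cbs <- build_codebook(emb, 30L, method = "subsample", seed = 1L)
  expect_equal(cbs$centroids, emb, ignore_attr = TRUE)
  expect_error(build_codebook(emb, 31L), "at least K")
})

test_that("k-means inertia is non-increasing over iterations", {
  set.seed(4)
  emb <- matrix(rnorm(200 * 6), 200)
  inertia <- vapply(c(1L, 3L, 10L, 25L), function(it) {
    set.seed(11)
    km <- suppressWarnings(stats::kmeans(emb, centers = 12L, iter.max = it,
                                         nstart = 1L))
    km$tot.withinss
  }, numeric(1))
  expect_true(all(diff(inertia) <= 1e-8))
})

test_that("quantization matches the brute-force nearest-centroid oracle", {
  set.seed(5)
  emb <- matrix(rnorm(40 * 8), 40)
  cb <- build_codebook(emb, 10L, seed = 2L)
  q <- quantize(emb, cb)
  oracle <- apply(emb, 1L, function(z) {
    d2 <- colSums((t(cb$centroids) - z)^2)
    which.min(d2)   # lowest index on ties
  })
  expect_equal(q$indices, unname(oracle))
  expect_equal(q$quantized, cb$centroids[oracle, ], ignore_attr = TRUE)
  # embeddings drawn from the codebook quantize to themselves
  sub <- cb$centroids[c(3, 7, 1), ]
  qs <- quantize(sub, cb)
  expect_equal(qs$indices, c(3L, 7L, 1L))
  expect_identical(qs$quantized, sub)
})

test_that("a full-embedding codebook quantizes with exactly zero error; nested codebooks never hurt", {
  set.seed(6)
  emb <- matrix(rnorm(25 * 8), 25)
  full <- build_codebook(emb, 25L, method = "subsample", seed = 1L)
  q <- quantize(emb, full)
  expect_equal(max(abs(q$quantized - emb)), 0)
  # nested subsample codebooks: enlarging the codebook cannot increase
  # total quantization error
  err <- vapply(c(5L, 10L, 25L), function(K) {
    cb <- build_codebook(emb[seq_len(K), , drop = FALSE], K,
                         method = "subsample", seed = 1L)
    sum((quantize(emb, cb)$quantized - emb)^2)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-10))
})

test_that("Frechet distance: zero on identical sets, symmetric, univariate closed form", {
  set.seed(7)
  z <- matrix(rnorm(60 * 5), 60)
  types <- rep(c("ALA", "GLY", "SER"), each = 20)
  d0 <- frechet_protein_distance(z, types, z, types)
  expect_equal(unname(d0), rep(0, 3), tolerance = 1e-8)
  z2 <- matrix(rnorm(60 * 5, mean = 0.5), 60)
  dab <- frechet_protein_distance(z, types, z2, types)
  dba <- frechet_protein_distance(z2, types, z, types)
  expect_equal(dab, dba[names(dab)], tolerance = 1e-8)
  # exact moments: N(0,1) vs N(3,4) -> 9 + (1 + 4 - 2*2) = 10
  expect_equal(frechet_gaussian(0, matrix(1), 3, matrix(4)), 10,
               tolerance = 1e-12)
  expect_warning(
    frechet_protein_distance(z[1, , drop = FALSE], "ALA", z, types),
    "skipped")
})

test_that("native-decoy margin is 0 for identical and 1 for orthogonal decoys, monotone in noise", {
  s <- test_peptide("ACDEFGHIKLMN", "helix", seed = 2L)
  cfg <- encoder_config(n_layers = 1L, scalar_dim = 16L, n_channels = 4L,
                        lmax = 1L, n_basis = 4L, cutoff = 6,
                        residue_dim = 16L, seed = 3L)
  params <- init_encoder_params(cfg)
  zn <- encode(s, cfg, params = params)
  m0 <- native_decoy_margin(zn, list(zn, zn))
  expect_equal(m0$per_residue, rep(0, s$n_residues), tolerance = 1e-12)
  # orthogonal embeddings -> margin 1
  orth <- zn$z
  orth[] <- 0; orth[, 1] <- 1
  base <- matrix(0, nrow(orth), ncol(orth)); base[, 2] <- 1
  m1 <- native_decoy_margin(base, list(orth))
  expect_equal(m1$per_residue, rep(1, nrow(orth)))
  # noisier decoys never look more native (Monte Carlo over seeds)
  sched <- c(0.2, 0.8, 2)
  margins <- rep(0, length(sched))
  for (rep_i in 1:20) {
    ds <- make_decoy_set(s, length(sched), sched, seed = 500L + rep_i)
    zs <- lapply(ds, function(d) encode(d, cfg, params = params))
    for (k in seq_along(sched)) {
      margins[k] <- margins[k] +
        native_decoy_margin(zn, zs[k])$mean / 20
    }
  }
  expect_true(all(diff(margins) > 0))
  expect_error(native_decoy_margin(zn, list(matrix(0, 2, 2))),
               "misaligned")
})
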