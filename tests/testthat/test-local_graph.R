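test_that("edge sets equal the brute-force all-pairs filter on random clouds", {
  for (seed in 1:5) {
    tab <- random_cloud(50L, seed = seed, spread = 12)
    g <- build_local_graph(tab, cutoff = 5)
    oracle <- brute_force_edges(cbind(tab$x, tab$y, tab$z), 5)
    expect_equal(cbind(dst = g$edge_dst, src = g$edge_src),
                 oracle, ignore_attr = TRUE)
    # both directions present, no self-edges, distances in (0, cutoff]
    expect_true(all(g$edge_dst != g$edge_src))
    expect_true(all(g$edge_distance > 0 & g$edge_distance <= 5))
    expect_identical(g$edge_src[g$reverse_edge],
                     g$edge_dst)
    # unit vectors have unit norm
    expect_lt(max(abs(rowSums(g$edge_unit_vector^2) - 1)), 1e-12)
  }
})

test_that("two-atom cases produce exactly the edges the cutoff dictates", {
  tab <- data.frame(x = c(0, 5), y = 0, z = 0, element = "C",
                    residue = c(1L, 2L))
  expect_equal(length(build_local_graph(tab, cutoff = 8)$edge_src), 2L)
  tab9 <- transform(tab, x = c(0, 9))
  expect_equal(length(build_local_graph(tab9, cutoff = 8)$edge_src), 0L)
})

test_that("Bessel basis matches its closed form and vanishes at the cutoff", {
  expect_equal(bessel_basis(4, 1L, 8)[1, 1], 0.125, tolerance = 1e-12)
  # high-resolution grid comparison against direct formula evaluation
  r <- seq(0.1, 8, length.out = 200)
  got <- bessel_basis(r, 6L, 8)
  for (n in 1:6) {
    expect_equal(got[, n], sqrt(2 / 8) * sin(n * pi * r / 8) / r,
                 tolerance = 1e-12)
  }
  expect_lt(max(abs(bessel_basis(8, 8L, 8))), 1e-12)
  expect_error(bessel_basis(0, 4L, 8), "r > 0")
})

test_that("spherical harmonics have the right sizes, constant l=0, and l=1 rotation equivariance", {
  v <- c(0.3, -0.5, 0.81); v <- v / sqrt(sum(v^2))
  w <- c(-0.7, 0.1, 0.6); w <- w / sqrt(sum(w^2))
  expect_equal(length(spherical_harmonic_features(v, 2L)), 9L)
  expect_equal(spherical_harmonic_features(v, 0L),
               spherical_harmonic_features(w, 0L))
  # explicit rotation oracle on the l=1 block
  R <- random_rigid_motion(13)$rotation
  y1 <- spherical_harmonic_features(as.numeric(R %*% v), 1L)[2:4]
  D1 <- real_wigner_d(1L, R)
  y0 <- spherical_harmonic_features(v, 1L)[2:4]
  expect_equal(y1, as.numeric(D1 %*% y0), tolerance = 1e-12)
  # the l=1 representation is the rotation itself in (y, z, x) ordering
  perm <- c(2, 3, 1)
  expect_equal(D1, R[perm, perm], tolerance = 1e-12)
  expect_error(spherical_harmonic_features(c(0, 0, 0), 1L), "zero")
})

test_that("cutoff envelope meets its boundary contract", {
  expect_equal(cutoff_envelope(0, 8), 1)
  expect_equal(cutoff_envelope(8, 8), 0)
  expect_equal(cutoff_envelope(10, 8), 0)
  # zero first derivative at the cutoff (central finite difference)
  h <- 1e-5
  deriv <- (cutoff_envelope(8 + h, 8) - cutoff_envelope(8 - h, 8)) / (2 * h)
  expect_lt(abs(deriv), 1e-4)
  r <- seq(0, 8, length.out = 100)
  expect_true(all(diff(cutoff_envelope(r, 8)) <= 0))
})

test_that("radial features are rigid-motion invariant and angular features equivariant", {
  s <- test_peptide("ACDEFG", "helix")
  g <- build_local_graph(s, cutoff = 6)
  rt <- random_rigid_motion(17)
  g2 <- build_local_graph(transform_structure(s, rt$rotation,
                                              rt$translation), cutoff = 6)
  expect_equal(g2$edge_distance, g$edge_distance, tolerance = 1e-9)
  expect_equal(g2$edge_radial, g$edge_radial, tolerance = 1e-9)
  for (l in 0:2) {
    cols <- (l^2 + 1):((l + 1)^2)
    D <- real_wigner_d(l, rt$rotation)
    expect_equal(g2$edge_angular[, cols, drop = FALSE],
                 g$edge_angular[, cols, drop = FALSE] %*% t(D),
                 tolerance = 1e-9)
  }
})

test_that("graph construction is permutation-consistent", {
  tab <- random_cloud(40L, seed = 8)
  g <- build_local_graph(tab, cutoff = 6)
  set.seed(1); perm <- sample(40L)
  tabp <- tab[perm, ]
  gp <- build_local_graph(tabp, cutoff = 6)
  # same number of edges; every permuted edge maps to an original edge
  expect_equal(length(gp$edge_src), length(g$edge_src))
  orig_pairs <- paste(g$edge_dst, g$edge_src)
  mapped <- paste(perm[gp$edge_dst], perm[gp$edge_src])
  expect_setequal(mapped, orig_pairs)
})

test_that("degenerate graphs are rejected", {
  expect_error(build_local_graph(data.frame(x = numeric(0), y = numeric(0),
                                            z = numeric(0),
                                            element = character(0),
                                            residue = integer(0)),
                                 cutoff = 8), "no occupied")
  s <- test_peptide("AC")
  expect_error(build_local_graph(s, cutoff = -1), "cutoff")
})
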