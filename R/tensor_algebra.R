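# Real tensor algebra for the equivariant channel: Clebsch-Gordan coupling
# coefficients in the real spherical-harmonic basis, and numerically fitted
# real Wigner rotation matrices (used to verify, and in tests to assert,
# equivariance). Degrees are truncated at lmax <= 3.

cg_cache <- new.env(parent = emptyenv())

#' Real Clebsch-Gordan coupling tensor
#'
#' Coupling coefficients C[m1, m2, m3] in the real spherical-harmonic
#' basis: if a transforms as degree l1 and b as degree l2 under the real
#' Wigner matrices of [real_wigner_d()], then
#' `c[m3] = sum_{m1,m2} C[m1,m2,m3] a[m1] b[m2]` transforms as degree l3.
#'
#' The tensor is constructed as the (one-dimensional, for the supported
#' degree triples) null space of the intertwining constraint
#' `couple(D1 a, D2 b) = D3 couple(a, b)` stacked over a fixed set of
#' rotations, normalized to unit Frobenius norm with a fixed sign
#' convention; tensors are cached per degree triple.
#'
#' @param l1,l2,l3 degrees with |l1-l2| <= l3 <= l1+l2, each <= 3.
#' @return (2l1+1) x (2l2+1) x (2l3+1) array.
#' @export
real_cg_tensor <- function(l1, l2, l3) {
  key <- paste(l1, l2, l3, sep = "_")
  if (!is.null(cg_cache[[key]])) return(cg_cache[[key]])
  if (l3 < abs(l1 - l2) || l3 > l1 + l2) {
    stop("degrees violate the triangle rule")
  }
  d1 <- 2 * l1 + 1; d2 <- 2 * l2 + 1; d3 <- 2 * l3 + 1
  rots <- lapply(c(101L, 202L, 303L), function(s) random_rigid_motion(s)$rotation)
  K <- do.call(rbind, lapply(rots, function(R) {
    D1 <- real_wigner_d(l1, R); D2 <- real_wigner_d(l2, R)
    D3 <- real_wigner_d(l3, R)
    # vec(C) with m1 fastest, then m2, then m3
    kronecker(diag(d3), kronecker(t(D2), t(D1))) -
      kronecker(D3, diag(d1 * d2))
  }))
  sv <- svd(K)
  vals <- sv$d
  if (vals[length(vals)] > 1e-8 ||
      (length(vals) > 1 && vals[length(vals) - 1] < 1e-8)) {
    stop("equivariant coupling space is not one-dimensional for (",
         l1, ",", l2, ",", l3, ")")
  }
  v <- sv$v[, ncol(sv$v)]
  v[abs(v) < 1e-12] <- 0
  lead <- v[which(abs(v) > 1e-8)[1L]]
  v <- v / sign(lead)
  out <- array(v, dim = c(d1, d2, d3))
  cg_cache[[key]] <- out
  out
}

#' Real Wigner rotation matrix of degree l
#'
#' The (2l+1) x (2l+1) matrix D with Y_l(R v) = D %*% Y_l(v) for the
#' package's real spherical harmonics, obtained by exact linear solve on
#' evaluation points. Used to state and test equivariance.
#'
#' @param l degree (0..3).
#' @param rotation 3 x 3 proper rotation matrix.
#' @return rotation representation matrix.
#' @export
real_wigner_d <- function(l, rotation) {
  if (l == 0L) return(matrix(1, 1, 1))
  d <- 2 * l + 1
  set_pts <- local({  # fixed, well-conditioned unit directions
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(20240301L)
    m <- matrix(stats::rnorm(3 * (d + 10)), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  A <- spherical_harmonic_features(set_pts, lmax = l)
  cols <- (l^2 + 1):(l^2 + d)
  Yv <- A[, cols, drop = FALSE]
  rot_pts <- set_pts %*% t(rotation)
  Yr <- spherical_harmonic_features(rot_pts, lmax = l)[, cols, drop = FALSE]
  # solve D: Yr = Yv %*% t(D)
  t(qr.solve(Yv, Yr))
}
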