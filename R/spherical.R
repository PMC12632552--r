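# Geometric edge features: Bessel radial basis vanishing at the cutoff,
# real spherical harmonics of the interatomic direction, and the smooth
# cutoff envelope that gates messages as atoms cross the neighborhood
# boundary.

#' Bessel radial basis
#'
#' Component n is sqrt(2/c) * sin(n*pi*r/c) / r for n = 1..n_basis with
#' c the cutoff; every component vanishes at r = c.
#'
#' @param r distances in Angstrom (vector ok); must be > 0 and <= cutoff.
#' @param n_basis number of basis functions (>= 1).
#' @param cutoff cutoff radius in Angstrom.
#' @return length(r) x n_basis matrix of coefficients.
#' @export
bessel_basis <- function(r, n_basis = 8L, cutoff = 8) {
  if (any(r <= 0)) stop("bessel_basis requires r > 0")
  if (n_basis < 1L) stop("n_basis must be >= 1")
  n <- seq_len(n_basis)
  out <- outer(r, n, function(ri, ni) {
    sqrt(2 / cutoff) * sin(ni * pi * ri / cutoff) / ri
  })
  dim(out) <- c(length(r), n_basis)
  out
}

# orthonormal real spherical harmonics on the unit sphere, cartesian
# closed forms up to l = 3 (standard phase conventions, m = -l..l)
SH_LMAX_SUPPORTED <- 3L

#' Real spherical harmonics of a direction
#'
#' Evaluates the orthonormal real spherical harmonics Y_lm for
#' l = 0..lmax at unit direction(s), concatenated in order
#' (l, m = -l..l); total length (lmax+1)^2.
#'
#' @param direction unit 3-vector, or an m x 3 matrix of unit rows.
#' @param lmax maximum degree (0..3 supported).
#' @return coefficient vector, or m x (lmax+1)^2 matrix for matrix input.
#' @export
spherical_harmonic_features <- function(direction, lmax = 2L) {
  if (lmax < 0L || lmax > SH_LMAX_SUPPORTED) {
    stop("lmax must be in 0..", SH_LMAX_SUPPORTED)
  }
  one <- is.null(dim(direction))
  v <- if (one) matrix(direction, 1, 3) else as.matrix(direction)
  stopifnot(ncol(v) == 3)
  nr <- sqrt(rowSums(v^2))
  if (any(nr < 1e-8)) stop("zero direction vector")
  if (any(abs(nr - 1) > 1e-6)) stop("direction must be a unit vector")
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  cols <- list(rep(0.28209479177387814, nrow(v)))
  if (lmax >= 1L) {
    c1 <- 0.4886025119029199
    cols <- c(cols, list(c1 * y, c1 * z, c1 * x))
  }
  if (lmax >= 2L) {
    cols <- c(cols, list(
      1.0925484305920792 * x * y,
      1.0925484305920792 * y * z,
      0.31539156525252005 * (3 * z^2 - 1),
      1.0925484305920792 * x * z,
      0.5462742152960396 * (x^2 - y^2)
    ))
  }
  if (lmax >= 3L) {
    cols <- c(cols, list(
      0.5900435899266435 * y * (3 * x^2 - y^2),
      2.890611442640554 * x * y * z,
      0.4570457994644658 * y * (5 * z^2 - 1),
      0.3731763325901154 * z * (5 * z^2 - 3),
      0.4570457994644658 * x * (5 * z^2 - 1),
      1.445305721320277 * z * (x^2 - y^2),
      0.5900435899266435 * x * (x^2 - 3 * y^2)
    ))
  }
  out <- do.call(cbind, cols)
  if (one) drop(out) else out
}

#' Smooth cutoff envelope
#'
#' u(r) = (1 - (r/c)^2)^3 on [0, c], 0 beyond: value 1 at r = 0,
#' monotonically non-increasing, and 0 with zero first derivative at
#' r = c, so gated features vary continuously as atoms cross the
#' neighborhood boundary.
#'
#' @param r distances (vector ok), r >= 0.
#' @param cutoff cutoff radius in Angstrom.
#' @return envelope values in [0, 1].
#' @export
cutoff_envelope <- function(r, cutoff = 8) {
  if (any(r < 0)) stop("cutoff_envelope requires r >= 0")
  t2 <- pmin(r / cutoff, 1)^2
  (1 - t2)^3
}
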