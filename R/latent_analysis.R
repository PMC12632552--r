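# Latent-space tooling: post-hoc kNN codebooks on frozen encoder
# embeddings, linear interpolation between conformational states with
# decoding, per-residue-type Frechet distance between embedding
# distributions, and native-decoy cosine margins.

#' Linear interpolation path between two embedding sets
#'
#' z_i(t) = (1 - t) z_i(A) + t z_i(B), per residue, at evenly spaced
#' t in [0, 1] including both endpoints: Z(0) = Z(A) and Z(1) = Z(B)
#' exactly.
#'
#' @param zA,zB n x d matrices (or `residue_embeddings`).
#' @param steps number of frames (>= 2; default 50).
#' @return object of class `interpolation_path`: list with `t` (length
#'   `steps`) and `frames` (list of n x d matrices).
#' @export
interpolate <- function(zA, zB, steps = 50L) {
  if (inherits(zA, "residue_embeddings")) zA <- zA$z
  if (inherits(zB, "residue_embeddings")) zB <- zB$z
  if (!all(dim(zA) == dim(zB))) stop("embedding shapes differ")
  if (steps < 2L) stop("need at least 2 interpolation steps")
  ts <- seq(0, 1, length.out = steps)
  frames <- lapply(ts, function(t) {
    if (t == 0) zA else if (t == 1) zB else (1 - t) * zA + t * zB
  })
  structure(list(t = ts, frames = frames), class = "interpolation_path")
}

#' Build a codebook on frozen embeddings
#'
#' Centroids by k-means (default) or seeded subsampling; deterministic
#' given the seed.
#'
#' @param embeddings M x d matrix of pooled residue embeddings.
#' @param K codebook size (<= M).
#' @param method "kmeans" or "subsample".
#' @param seed integer seed.
#' @param iter_max k-means iteration cap.
#' @return object of class `codebook`: list with `centroids` (K x d),
#'   `K`, `method`, `seed`, `source_count`.
#' @export
build_codebook <- function(embeddings, K, method = c("kmeans", "subsample"),
                           seed = 1L, iter_max = 50L) {
  method <- match.arg(method)
  embeddings <- as.matrix(embeddings)
  M <- nrow(embeddings)
  if (M < K) stop("need at least K embeddings to build a K-codebook")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  centroids <- if (method == "subsample") {
    embeddings[sort(sample.int(M, K)), , drop = FALSE]
  } else if (K == M) {
    embeddings
  } else {
    km <- stats::kmeans(embeddings, centers = K, iter.max = iter_max,
                        nstart = 1L)
    km$centers
  }
  dimnames(centroids) <- NULL
  structure(list(centroids = centroids, K = as.integer(K),
                 method = method, seed = as.integer(seed),
                 source_count = M), class = "codebook")
}

#' Quantize embeddings against a codebook
#'
#' Each row is replaced by its nearest centroid (Euclidean distance);
#' ties break to the lowest centroid index.
#'
#' @param embeddings n x d matrix (or `residue_embeddings`).
#' @param codebook a [build_codebook()] result.
#' @return list with `indices` (length n) and `quantized` (n x d).
#' @export
quantize <- function(embeddings, codebook) {
  if (inherits(embeddings, "residue_embeddings")) {
    embeddings <- embeddings$z
  }
  z <- as.matrix(embeddings)
  cb <- codebook$centroids
  # squared distances via the expansion ||z||^2 - 2 z.c + ||c||^2
  d2 <- outer(rowSums(z^2), rowSums(cb^2), "+") - 2 * tcrossprod(z, cb)
  idx <- max.col(-d2, ties.method = "first")
  list(indices = idx, quantized = cb[idx, , drop = FALSE])
}

#' Gaussian Frechet distance between two moment pairs
#'
#' ||muA - muB||^2 + Tr(SA + SB - 2 (SA SB)^(1/2)), computed through the
#' symmetric product eigendecomposition.
#'
#' @param muA,muB mean vectors.
#' @param SA,SB covariance matrices.
#' @return non-negative scalar.
#' @export
frechet_gaussian <- function(muA, SA, muB, SB) {
  SA <- as.matrix(SA); SB <- as.matrix(SB)
  eA <- eigen(SA, symmetric = TRUE)
  rootA <- eA$vectors %*% (sqrt(pmax(eA$values, 0)) * t(eA$vectors))
  M <- rootA %*% SB %*% rootA
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_cross <- sum(sqrt(pmax(ev, 0)))
  sum((muA - muB)^2) + sum(diag(SA)) + sum(diag(SB)) - 2 * tr_cross
}

#' Per-residue-type Frechet protein distance
#'
#' For each residue type present on both sides with at least `min_n`
#' samples, the Gaussian Frechet (Wasserstein-2) distance between the
#' embedding distributions, on covariances regularized by `eps * I`.
#' Types with too few samples are skipped with a warning.
#'
#' @param zA m x d embeddings with `typesA` labels (three-letter codes);
#' @param zB k x d embeddings with `typesB` labels.
#' @param typesA,typesB residue-type labels (ground-truth sequences).
#' @param eps covariance regularization (default 1e-6).
#' @param min_n minimum samples per side per type (default 2).
#' @return named numeric vector of distances, one entry per compared
#'   residue type.
#' @export
frechet_protein_distance <- function(zA, typesA, zB, typesB,
                                     eps = 1e-6, min_n = 2L) {
  zA <- as.matrix(zA); zB <- as.matrix(zB)
  stopifnot(nrow(zA) == length(typesA), nrow(zB) == length(typesB))
  shared <- intersect(unique(typesA), unique(typesB))
  out <- numeric(0)
  for (tp in shared) {
    a <- zA[typesA == tp, , drop = FALSE]
    b <- zB[typesB == tp, , drop = FALSE]
    if (nrow(a) < min_n || nrow(b) < min_n) {
      warning("residue type ", tp, " skipped: fewer than ", min_n,
              " samples")
      next
    }
    SA <- stats::cov(a) + eps * diag(ncol(a))
    SB <- stats::cov(b) + eps * diag(ncol(b))
    out[tp] <- frechet_gaussian(colMeans(a), SA, colMeans(b), SB)
  }
  out
}

#' Native-decoy cosine margin
#'
#' Default definition: margin_i = 1 - mean over decoys of
#' cos(z_i(native), z_i(decoy)), reported per residue and averaged.
#' The statistic admits variants; `aggregate` selects the mean (default)
#' or the minimum cosine over decoys, and the chosen definition is
#' recorded in the result.
#'
#' @param native `residue_embeddings` (or n x d matrix) of the native.
#' @param decoys list of embeddings aligned to the same residue
#'   positions.
#' @param aggregate "mean" or "min" cosine over decoys.
#' @return list with `per_residue` (length n), `mean` and `definition`.
#' @export
native_decoy_margin <- function(native, decoys, aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  zn <- if (inherits(native, "residue_embeddings")) native$z else
    as.matrix(native)
  dz <- lapply(decoys, function(d) {
    z <- if (inherits(d, "residue_embeddings")) d$z else as.matrix(d)
    if (!all(dim(z) == dim(zn))) {
      stop("decoy embeddings misaligned with native residue positions")
    }
    z
  })
  nn <- sqrt(rowSums(zn^2))
  cosines <- vapply(dz, function(z) {
    rowSums(zn * z) / (nn * sqrt(rowSums(z^2)))
  }, numeric(nrow(zn)))
  cosines <- matrix(cosines, nrow = nrow(zn))
  agg <- if (aggregate == "mean") rowMeans(cosines) else
    apply(cosines, 1L, min)
  per <- 1 - agg
  list(per_residue = per, mean = mean(per),
       definition = paste0("1 - ", aggregate, " cosine over decoys"))
}

#' Decode every frame of an interpolation path
#'
#' @param path an [interpolate()] result.
#' @param config a [decoder_config()].
#' @param params decoder parameters.
#' @param residue_types passed to [decode()].
#' @return list of `decoder_output`, one per frame.
#' @export
decode_path <- function(path, config, params, residue_types = NULL) {
  stopifnot(inherits(path, "interpolation_path"))
  lapply(path$frames, function(z) {
    decode(z, config, params = params, residue_types = residue_types)
  })
}
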