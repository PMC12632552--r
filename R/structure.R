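#' All-atom structure container
#'
#' Bundles a protein chain (or several) as per-residue atom-37 coordinate
#' blocks with an occupancy mask. Coordinates are in Angstrom throughout;
#' masked-out slots carry no meaningful coordinates and are excluded from
#' every distance and loss computation in the package.
#'
#' @param residue_types character vector of three-letter codes (length n).
#' @param coords numeric array n x 37 x 3 (Angstrom). Masked slots may hold
#'   any value (conventionally 0).
#' @param atom_mask logical matrix n x 37; TRUE where the slot is occupied.
#' @param chain_labels character vector of length n (default all "A").
#' @return an object of class `all_atom_structure` with fields
#'   `n_residues`, `residue_types`, `chain_labels`, `coords`, `atom_mask`.
#' @export
all_atom_structure <- function(residue_types, coords, atom_mask,
                               chain_labels = NULL) {
  residue_types <- toupper(residue_types)
  n <- length(residue_types)
  if (n < 1L) stop("structure must contain at least one residue")
  if (!all(residue_types %in% AA3)) {
    stop("non-canonical residue type(s): ",
         paste(setdiff(residue_types, AA3), collapse = ", "))
  }
  if (is.null(chain_labels)) chain_labels <- rep("A", n)
  chain_labels <- as.character(chain_labels)
  chain_labels[!nzchar(chain_labels)] <- "A"
  stopifnot(length(chain_labels) == n)
  coords <- array(as.numeric(coords), dim = c(n, 37L, 3L))
  atom_mask <- matrix(as.logical(atom_mask), nrow = n, ncol = 37L)
  if (any(is.na(atom_mask))) stop("atom_mask must not contain NA")
  # an occupied slot must be one the residue chemistry allows
  for (i in seq_len(n)) {
    allowed <- atom37_mask_row(residue_types[i])
    if (any(atom_mask[i, ] & !allowed)) {
      stop("residue ", i, " (", residue_types[i],
           ") occupies slots outside its template")
    }
  }
  coords[!rep_mask3(atom_mask)] <- 0
  structure(
    list(n_residues = n, residue_types = residue_types,
         chain_labels = chain_labels, coords = coords,
         atom_mask = atom_mask),
    class = "all_atom_structure"
  )
}

# expand an n x 37 mask to n x 37 x 3
rep_mask3 <- function(mask) {
  array(rep(mask, 3L), dim = c(dim(mask), 3L))
}

#' @export
print.all_atom_structure <- function(x, ...) {
  cat("<all_atom_structure> ", x$n_residues, " residues, ",
      sum(x$atom_mask), " heavy atoms, chains: ",
      paste(unique(x$chain_labels), collapse = ","), "\n", sep = "")
  cat("  sequence: ", paste(aa3_to_aa1(x$residue_types), collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Flat table of the occupied atoms of a structure
#'
#' @param structure an `all_atom_structure`.
#' @return data.frame with columns residue (index), slot (1..37),
#'   atom_name, element, residue_type, chain, x, y, z, in residue-major
#'   slot-minor order.
#' @export
atom_table <- function(structure) {
  stopifnot(inherits(structure, "all_atom_structure"))
  idx <- which(t(structure$atom_mask))  # slot-fastest within residue
  slot <- (idx - 1L) %% 37L + 1L
  res <- (idx - 1L) %/% 37L + 1L
  xyz <- matrix(0, length(idx), 3L)
  for (k in 1:3) xyz[, k] <- structure$coords[cbind(res, slot, k)]
  data.frame(
    residue = res,
    slot = slot,
    atom_name = ATOM37_NAMES[slot],
    element = atom37_elements()[slot],
    residue_type = structure$residue_types[res],
    chain = structure$chain_labels[res],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
}

#' Apply a rigid motion (or general linear map + shift) to a structure
#'
#' @param structure an `all_atom_structure`.
#' @param rotation 3 x 3 matrix (for a proper rigid motion, a rotation).
#' @param translation length-3 numeric.
#' @return transformed `all_atom_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "all_atom_structure"))
  n <- structure$n_residues
  flat <- matrix(aperm(structure$coords, c(3, 2, 1)), nrow = 3)  # 3 x (37 n)
  flat <- rotation %*% flat + translation
  coords <- aperm(array(flat, dim = c(3, 37, n)), c(3, 2, 1))
  out <- structure
  out$coords <- coords
  out$coords[!rep_mask3(out$atom_mask)] <- 0
  out
}

#' Random proper rigid motion
#'
#' @param seed integer seed; the rotation is drawn uniformly (QR of a
#'   Gaussian matrix, sign-fixed to det +1) and the translation from
#'   N(0, 10 Angstrom).
#' @return list(rotation, translation).
#' @export
random_rigid_motion <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = stats::rnorm(3, sd = 10))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' All-atom RMSD between two structures
#'
#' Root-mean-square deviation over the jointly occupied atom-37 slots.
#' By default the structures are first optimally superposed (Kabsch
#' algorithm), making the value invariant to any proper rigid motion of
#' either argument; set `superpose = FALSE` for the raw deviation in the
#' given frames.
#'
#' @param a,b `all_atom_structure` objects with identical residue_types
#'   and atom_mask.
#' @param superpose logical; optimal rigid superposition first (default
#'   TRUE).
#' @return RMSD in Angstrom.
#' @export
all_atom_rmsd <- function(a, b, superpose = TRUE) {
  stopifnot(inherits(a, "all_atom_structure"),
            inherits(b, "all_atom_structure"))
  if (a$n_residues != b$n_residues ||
      !identical(a$residue_types, b$residue_types) ||
      !identical(a$atom_mask, b$atom_mask)) {
    stop("incompatible structures: residue types or atom masks differ")
  }
  xa <- structure_coord_matrix(a)
  xb <- structure_coord_matrix(b)
  rmsd_points(xa, xb, superpose = superpose)
}

# m x 3 matrix of occupied coordinates, residue-major slot-minor order
structure_coord_matrix <- function(structure) {
  tab <- atom_table(structure)
  cbind(tab$x, tab$y, tab$z)
}

#' RMSD between two matched point sets
#'
#' @param xa,xb m x 3 matrices of matched points.
#' @param superpose Kabsch superposition first (default TRUE).
#' @return RMSD of the matched points.
#' @export
rmsd_points <- function(xa, xb, superpose = TRUE) {
  stopifnot(nrow(xa) == nrow(xb), ncol(xa) == 3, ncol(xb) == 3)
  if (superpose) xb <- kabsch_align(xb, xa)
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Optimally superpose one point set onto another (Kabsch)
#'
#' @param x m x 3 points to move.
#' @param target m x 3 reference points.
#' @return the moved copy of `x` minimizing RMSD to `target` over proper
#'   rigid motions.
#' @export
kabsch_align <- function(x, target) {
  cx <- colMeans(x); ct <- colMeans(target)
  xc <- sweep(x, 2, cx); tc <- sweep(target, 2, ct)
  s <- svd(crossprod(xc, tc))  # 3x3
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(xc %*% t(R), 2, ct, FUN = "+")
}
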