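# Synthetic all-atom peptide generator. Builds idealized polypeptides from
# internal coordinates: preset backbone dihedrals (helix / strand / coil),
# ideal covalent geometry, and templated side chains with seeded rotamers.
# Every training and analysis path in the package is testable on these
# fixtures without any external structure download.

# Per-residue side-chain z-matrices: atom placed from (p, a, d) references
# with the given bond (A) / angle (deg); `dih` is a fixed torsion unless
# `chi` names a sampled torsion index, in which case the placed torsion is
# chi_k + dih (dih then acts as a branch offset, usually 0).
# Values follow standard ideal stereochemistry.
sc_entry <- function(atom, p, a, d, bond, angle, dih, chi = NA_integer_) {
  list(atom = atom, p = p, a = a, d = d, bond = bond, angle = angle,
       dih = dih, chi = chi)
}

SIDECHAIN_ZMAT <- list(
  ALA = list(),
  SER = list(sc_entry("OG", "CB", "CA", "N", 1.428, 109.5, 0, 1L)),
  CYS = list(sc_entry("SG", "CB", "CA", "N", 1.814, 109.5, 0, 1L)),
  VAL = list(sc_entry("CG1", "CB", "CA", "N", 1.530, 109.5, 0, 1L),
             sc_entry("CG2", "CB", "CA", "CG1", 1.529, 109.5, 120)),
  THR = list(sc_entry("OG1", "CB", "CA", "N", 1.428, 109.5, 0, 1L),
             sc_entry("CG2", "CB", "CA", "OG1", 1.530, 109.5, -120)),
  ILE = list(sc_entry("CG1", "CB", "CA", "N", 1.529, 109.5, 0, 1L),
             sc_entry("CG2", "CB", "CA", "CG1", 1.530, 109.5, -120),
             sc_entry("CD1", "CG1", "CB", "CA", 1.529, 109.5, 0, 2L)),
  LEU = list(sc_entry("CG", "CB", "CA", "N", 1.530, 109.5, 0, 1L),
             sc_entry("CD1", "CG", "CB", "CA", 1.530, 109.5, 0, 2L),
             sc_entry("CD2", "CG", "CB", "CD1", 1.529, 109.5, 120)),
  ASP = list(sc_entry("CG", "CB", "CA", "N", 1.508, 109.5, 0, 1L),
             sc_entry("OD1", "CG", "CB", "CA", 1.220, 120.0, 0, 2L),
             sc_entry("OD2", "CG", "CB", "OD1", 1.250, 120.0, 180)),
  ASN = list(sc_entry("CG", "CB", "CA", "N", 1.507, 109.5, 0, 1L),
             sc_entry("OD1", "CG", "CB", "CA", 1.213, 120.0, 0, 2L),
             sc_entry("ND2", "CG", "CB", "OD1", 1.348, 120.0, 180)),
  GLU = list(sc_entry("CG", "CB", "CA", "N", 1.531, 109.4, 0, 1L),
             sc_entry("CD", "CG", "CB", "CA", 1.508, 109.4, 0, 2L),
             sc_entry("OE1", "CD", "CG", "CB", 1.220, 120.0, 0, 3L),
             sc_entry("OE2", "CD", "CG", "OE1", 1.250, 120.0, 180)),
  GLN = list(sc_entry("CG", "CB", "CA", "N", 1.528, 109.5, 0, 1L),
             sc_entry("CD", "CG", "CB", "CA", 1.507, 109.5, 0, 2L),
             sc_entry("OE1", "CD", "CG", "CB", 1.212, 120.0, 0, 3L),
             sc_entry("NE2", "CD", "CG", "OE1", 1.347, 120.0, 180)),
  LYS = list(sc_entry("CG", "CB", "CA", "N", 1.531, 109.4, 0, 1L),
             sc_entry("CD", "CG", "CB", "CA", 1.531, 109.4, 0, 2L),
             sc_entry("CE", "CD", "CG", "CB", 1.529, 109.5, 0, 3L),
             sc_entry("NZ", "CE", "CD", "CG", 1.469, 109.5, 0, 4L)),
  MET = list(sc_entry("CG", "CB", "CA", "N", 1.528, 109.5, 0, 1L),
             sc_entry("SD", "CG", "CB", "CA", 1.814, 109.5, 0, 2L),
             sc_entry("CE", "SD", "CG", "CB", 1.814, 100.0, 0, 3L)),
  ARG = list(sc_entry("CG", "CB", "CA", "N", 1.537, 114.5, 0, 1L),
             sc_entry("CD", "CG", "CB", "CA", 1.527, 112.4, 0, 2L),
             sc_entry("NE", "CD", "CG", "CB", 1.444, 111.0, 0, 3L),
             sc_entry("CZ", "NE", "CD", "CG", 1.406, 123.0, 180),
             sc_entry("NH1", "CZ", "NE", "CD", 1.391, 121.0, 180),
             sc_entry("NH2", "CZ", "NE", "NH1", 1.391, 119.8, 180)),
  PHE = list(sc_entry("CG", "CB", "CA", "N", 1.505, 109.5, 0, 1L),
             sc_entry("CD1", "CG", "CB", "CA", 1.382, 120.0, 0, 2L),
             sc_entry("CD2", "CG", "CD1", "CB", 1.383, 120.0, 180),
             sc_entry("CE1", "CD1", "CG", "CD2", 1.382, 120.0, 0),
             sc_entry("CE2", "CD2", "CG", "CD1", 1.382, 120.0, 0),
             sc_entry("CZ", "CE1", "CD1", "CG", 1.381, 120.0, 0)),
  TYR = list(sc_entry("CG", "CB", "CA", "N", 1.506, 109.5, 0, 1L),
             sc_entry("CD1", "CG", "CB", "CA", 1.382, 120.0, 0, 2L),
             sc_entry("CD2", "CG", "CD1", "CB", 1.383, 120.0, 180),
             sc_entry("CE1", "CD1", "CG", "CD2", 1.381, 120.0, 0),
             sc_entry("CE2", "CD2", "CG", "CD1", 1.381, 120.0, 0),
             sc_entry("CZ", "CE1", "CD1", "CG", 1.387, 120.0, 0),
             sc_entry("OH", "CZ", "CE1", "CD1", 1.358, 120.0, 180)),
  HIS = list(sc_entry("CG", "CB", "CA", "N", 1.510, 113.0, 0, 1L),
             sc_entry("ND1", "CG", "CB", "CA", 1.351, 120.3, 0, 2L),
             sc_entry("CD2", "CG", "ND1", "CB", 1.338, 109.7, 180),
             sc_entry("CE1", "ND1", "CG", "CD2", 1.337, 107.9, 0),
             sc_entry("NE2", "CE1", "ND1", "CG", 1.337, 107.6, 0)),
  TRP = list(sc_entry("CG", "CB", "CA", "N", 1.507, 109.4, 0, 1L),
             sc_entry("CD1", "CG", "CB", "CA", 1.343, 126.5, 0, 2L),
             sc_entry("CD2", "CG", "CD1", "CB", 1.464, 107.0, 180),
             sc_entry("NE1", "CD1", "CG", "CD2", 1.369, 109.9, 0),
             sc_entry("CE2", "CD2", "CG", "CD1", 1.407, 106.1, 0),
             sc_entry("CE3", "CD2", "CE2", "CG", 1.396, 119.9, 180),
             sc_entry("CZ2", "CE2", "CD2", "CE3", 1.391, 119.3, 0),
             sc_entry("CZ3", "CE3", "CD2", "CE2", 1.366, 119.8, 0),
             sc_entry("CH2", "CZ2", "CE2", "CD2", 1.377, 119.8, 0)),
  PRO = list(sc_entry("CG", "CB", "CA", "N", 1.543, 105.1, -23.8),
             sc_entry("CD", "CG", "CB", "CA", 1.544, 105.1, 0.0)),
  GLY = list()
)

# rotamer sets: sp3 chis from the three staggered states; planar/aromatic
# chi2 of the ring residues from the two perpendicular states
CHI_SP3 <- c(-60, 180, 60)
CHI_AROM <- c(90, -90)
AROM_CHI2 <- c("PHE", "TYR", "TRP", "HIS")
SP2_CHI2 <- c("ASP", "ASN")  # carboxyl/amide plane: keep near 0/ +-30
CHI_SP2 <- c(-30, 0, 30)

# ideal backbone covalent geometry (Engh-Huber-style)
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8,
  cb_bond = 1.530, cb_angle = 109.5, cb_dih = -120.0
)

#' Backbone dihedral specification
#'
#' Presets: helix (phi -57, psi -47), strand (-139, +135), coil (sampled
#' uniformly from broad allowed regions under the seed). Omega defaults to
#' trans (180 degrees) everywhere.
#'
#' @param preset "helix", "strand" or "coil"; ignored when phi/psi given.
#' @param n number of residues.
#' @param phi,psi,omega optional explicit per-residue torsions (degrees),
#'   recycled to length n.
#' @param seed integer seed for the coil preset.
#' @return object of class `backbone_spec` with per-residue phi, psi, omega.
#' @export
backbone_spec <- function(preset = c("helix", "strand", "coil"), n,
                          phi = NULL, psi = NULL, omega = NULL, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(phi) || is.null(psi)) {
    if (preset == "helix") {
      phi <- rep(-57, n); psi <- rep(-47, n)
    } else if (preset == "strand") {
      phi <- rep(-139, n); psi <- rep(135, n)
    } else {
      old <- get_rng_state(); on.exit(set_rng_state(old))
      set.seed(as.integer(seed))
      phi <- stats::runif(n, -160, -50)
      psi <- stats::runif(n, -80, 170)
    }
  }
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  omega <- if (is.null(omega)) rep(180, n) else rep_len(omega, n)
  structure(list(preset = preset, n = n, phi = phi, psi = psi,
                 omega = omega), class = "backbone_spec")
}

#' Build an idealized all-atom peptide
#'
#' Backbone atoms are placed from internal coordinates with ideal bond
#' lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom) and angles; side
#' chains are placed from per-residue-type templates with rotamer chi
#' angles drawn deterministically from the seed. All atom-37 slots of each
#' residue type are occupied.
#'
#' @param sequence amino-acid string over the 20 one-letter codes,
#'   length >= 2.
#' @param spec a `backbone_spec`, or a preset name passed on to
#'   [backbone_spec()].
#' @param seed integer seed controlling rotamer (and coil) sampling.
#' @return an [all_atom_structure()].
#' @export
build_ideal_peptide <- function(sequence, spec = "helix", seed = 1L) {
  seq1 <- strsplit(toupper(paste(sequence, collapse = "")), "")[[1]]
  if (length(seq1) < 2L) stop("sequence must have length >= 2")
  res3 <- aa1_to_aa3(seq1)  # errors on unknown letters
  n <- length(res3)
  if (is.character(spec)) spec <- backbone_spec(spec, n, seed = seed)
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$n != n) stop("backbone_spec length does not match sequence")

  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  # pre-draw rotamer chis, residue-major, so placement order cannot drift
  chis <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    chis[i, ] <- sample(CHI_SP3, 4, replace = TRUE)
    if (res3[i] %in% AROM_CHI2) chis[i, 2] <- sample(CHI_AROM, 1)
    if (res3[i] %in% SP2_CHI2) chis[i, 2] <- sample(CHI_SP2, 1)
    if (res3[i] %in% c("GLU", "GLN")) chis[i, 3] <- sample(CHI_SP2, 1)
  }

  g <- BB_GEOM
  coords <- array(0, dim = c(n, 37, 3))
  mask <- matrix(FALSE, n, 37)
  pos <- vector("list", n)  # named per-residue atom positions

  for (i in seq_len(n)) {
    p <- list()
    if (i == 1L) {
      p$N <- c(0, 0, 0)
      p$CA <- c(g$n_ca, 0, 0)
      th <- deg2rad(g$ang_n_ca_c)
      p$C <- p$CA + g$ca_c * c(-cos(th), sin(th), 0)
    } else {
      q <- pos[[i - 1L]]
      p$N <- place_atom(q$C, q$CA, q$N, g$c_n, g$ang_ca_c_n,
                        spec$psi[i - 1L])
      p$CA <- place_atom(p$N, q$C, q$CA, g$n_ca, g$ang_c_n_ca,
                         spec$omega[i - 1L])
      p$C <- place_atom(p$CA, p$N, q$C, g$ca_c, g$ang_n_ca_c, spec$phi[i])
    }
    p$O <- place_atom(p$C, p$CA, p$N, g$c_o, g$ang_ca_c_o,
                      spec$psi[i] + 180)
    if (res3[i] != "GLY") {
      if (res3[i] == "PRO") {
        p$CB <- place_atom(p$CA, p$N, p$C, 1.543, 104.7, -118.8)
      } else {
        p$CB <- place_atom(p$CA, p$N, p$C, g$cb_bond, g$cb_angle, g$cb_dih)
      }
    }
    for (e in SIDECHAIN_ZMAT[[res3[i]]]) {
      dih <- if (is.na(e$chi)) e$dih else chis[i, e$chi] + e$dih
      if (res3[i] == "PRO" && !is.na(e$chi)) dih <- e$dih  # ring fixed
      p[[e$atom]] <- place_atom(p[[e$p]], p[[e$a]], p[[e$d]],
                                e$bond, e$angle, dih)
    }
    # PRO chi1 is fixed by the ring; override the sampled value
    if (res3[i] == "PRO") {
      p$CG <- place_atom(p$CB, p$CA, p$N, 1.543, 105.1, -23.8)
      p$CD <- place_atom(p$CG, p$CB, p$CA, 1.544, 105.1, 0.0)
    }
    pos[[i]] <- p
    for (nm in names(p)) {
      s <- match(nm, ATOM37_NAMES)
      coords[i, s, ] <- p[[nm]]
      mask[i, s] <- TRUE
    }
  }
  all_atom_structure(res3, coords, mask)
}

#' Two conformations of the same sequence
#'
#' Builds the sequence under two different backbone presets (helix and
#' strand) with identical rotamer seeds, so the pair differs in
#' conformation only: residue types and atom masks are identical.
#'
#' @param sequence amino-acid string, length >= 8.
#' @param seed integer seed (shared by both builds).
#' @param presets length-2 character of backbone presets.
#' @return list of two [all_atom_structure()] objects.
#' @export
make_conformer_pair <- function(sequence, seed = 1L,
                                presets = c("helix", "strand")) {
  seq1 <- strsplit(toupper(paste(sequence, collapse = "")), "")[[1]]
  if (length(seq1) < 8L) stop("conformer pairs need length >= 8")
  stopifnot(length(presets) == 2L)
  list(
    A = build_ideal_peptide(sequence, presets[1L], seed = seed),
    B = build_ideal_peptide(sequence, presets[2L], seed = seed)
  )
}

#' Perturbed decoys of a native structure
#'
#' Each decoy is the native with Gaussian atom noise of the given scale
#' plus random backbone dihedral kicks whose magnitude grows with the same
#' scale. Decoys are returned in order of increasing noise; a zero scale
#' reproduces the native exactly. Atom masks are preserved.
#'
#' @param native an [all_atom_structure()].
#' @param n_decoys number of decoys (>= 1).
#' @param noise_schedule numeric vector of Angstrom scales, length
#'   n_decoys (sorted ascending internally).
#' @param seed integer seed.
#' @param n_kicks dihedral kicks per decoy (default 3).
#' @return list of `all_atom_structure` decoys.
#' @export
make_decoy_set <- function(native, n_decoys,
                           noise_schedule = seq(0.2, 2, length.out = n_decoys),
                           seed = 1L, n_kicks = 3L) {
  stopifnot(inherits(native, "all_atom_structure"), n_decoys >= 1L)
  if (length(noise_schedule) != n_decoys) {
    stop("noise_schedule must have one scale per decoy")
  }
  if (any(noise_schedule < 0)) stop("noise scales must be >= 0")
  noise_schedule <- sort(noise_schedule)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  n <- native$n_residues
  lapply(noise_schedule, function(scale) {
    out <- native
    if (scale == 0) return(out)
    # backbone dihedral kicks: rotate everything downstream of a random
    # phi or psi bond
    for (k in seq_len(n_kicks)) {
      i <- sample.int(n - 1L, 1L)
      bond <- sample(c("phi", "psi"), 1L)
      ang <- deg2rad(stats::rnorm(1, sd = 4 * scale))
      if (bond == "phi") {
        a0 <- native_atom(out, i, "N"); a1 <- native_atom(out, i, "CA")
      } else {
        a0 <- native_atom(out, i, "CA"); a1 <- native_atom(out, i, "C")
      }
      R <- rotation_about_axis(a1 - a0, ang)
      for (j in (i + 1L):n) {
        occ <- which(out$atom_mask[j, ])
        xyz <- matrix(out$coords[j, occ, ], ncol = 3)
        xyz <- sweep(xyz, 2, a1)
        xyz <- xyz %*% t(R)
        out$coords[j, occ, ] <- sweep(xyz, 2, a1, FUN = "+")
      }
    }
    # isotropic Gaussian atom noise
    occ3 <- rep_mask3(out$atom_mask)
    noise <- array(stats::rnorm(length(out$coords), sd = scale),
                   dim = dim(out$coords))
    out$coords[occ3] <- out$coords[occ3] + noise[occ3]
    out
  })
}

native_atom <- function(structure, residue, atom_name) {
  s <- match(atom_name, ATOM37_NAMES)
  structure$coords[residue, s, ]
}

#' Covalently bonded atom pairs of a structure
#'
#' Derived from the backbone connectivity and the side-chain templates.
#' Useful for validating ideal-geometry invariants (all fixture bond
#' lengths fall in (0.8, 2.0) Angstrom).
#'
#' @param structure an [all_atom_structure()].
#' @return data.frame with residue/slot indices of both partners and the
#'   bond length.
#' @export
structure_bond_table <- function(structure) {
  n <- structure$n_residues
  rows <- list()
  add <- function(ri, ai, rj, aj) {
    si <- match(ai, ATOM37_NAMES); sj <- match(aj, ATOM37_NAMES)
    if (structure$atom_mask[ri, si] && structure$atom_mask[rj, sj]) {
      d <- vnorm(structure$coords[ri, si, ] - structure$coords[rj, sj, ])
      rows[[length(rows) + 1L]] <<- data.frame(
        res_i = ri, atom_i = ai, res_j = rj, atom_j = aj, length = d,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n)) {
    add(i, "N", i, "CA"); add(i, "CA", i, "C"); add(i, "C", i, "O")
    if (i < n) add(i, "C", i + 1L, "N")
    rt <- structure$residue_types[i]
    if (rt != "GLY") add(i, "CA", i, "CB")
    for (e in SIDECHAIN_ZMAT[[rt]]) add(i, e$atom, i, e$p)
    if (rt == "PRO") add(i, "CD", i, "N")
  }
  do.call(rbind, rows)
}
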