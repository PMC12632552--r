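# Inter-residue energy targets. Three channels per residue pair mirroring
# the physically motivated score terms used as regression targets:
# hydrogen bonding, electrostatics, and solvation. Values come from a
# documented surrogate labeler operating on interatomic geometry only
# (so tables are rigid-motion invariant); externally computed tables can
# be supplied through the tab-separated reader instead.

ENERGY_CHANNELS <- c("hbond", "electrostatics", "solvation")

#' Surrogate energy parameters
#'
#' @param elec_cutoff electrostatics pair cutoff (A).
#' @param coulomb_k Coulomb prefactor in kcal mol^-1 A e^-2; the screened
#'   interaction is `k q_i q_j / (eps(r) r)` with distance-dependent
#'   dielectric eps(r) = 4r.
#' @param hbond_cutoff donor-acceptor distance cutoff (A).
#' @param hbond_d0,hbond_sigma Gaussian optimum and width of the
#'   donor-acceptor distance term (A).
#' @param hbond_depth well depth (kcal/mol) of an ideal hydrogen bond.
#' @param solv_radius neighbor-count radius for atom burial (A).
#' @param solv_scale scale of the burial-product term.
#' @param clip symmetric clip range applied to every channel.
#' @return a `surrogate_params` list.
#' @export
surrogate_params <- function(elec_cutoff = 10, coulomb_k = 332,
                             hbond_cutoff = 4.0, hbond_d0 = 2.9,
                             hbond_sigma = 0.3, hbond_depth = 1.0,
                             solv_radius = 5, solv_scale = 0.001,
                             clip = 10) {
  structure(list(elec_cutoff = elec_cutoff, coulomb_k = coulomb_k,
                 hbond_cutoff = hbond_cutoff, hbond_d0 = hbond_d0,
                 hbond_sigma = hbond_sigma, hbond_depth = hbond_depth,
                 solv_radius = solv_radius, solv_scale = solv_scale,
                 clip = clip), class = "surrogate_params")
}

# minimal partial-charge lookup: backbone amide/carbonyl plus the charged
# side-chain termini of D/E/K/R/H
PARTIAL_CHARGES <- list(
  backbone = c(N = 0.35, O = -0.45),
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1.0),
  ARG = c(NE = 0.2, NH1 = 0.4, NH2 = 0.4),
  HIS = c(ND1 = 0.25, NE2 = 0.25)
)

# hydrogen-bond donors/acceptors with the antecedent heavy atom used for
# the angular factor
HB_DONORS <- list(
  backbone = list(c("N", "CA")),
  SER = list(c("OG", "CB")), THR = list(c("OG1", "CB")),
  TYR = list(c("OH", "CZ")), LYS = list(c("NZ", "CE")),
  ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
  HIS = list(c("ND1", "CG"), c("NE2", "CE1")),
  TRP = list(c("NE1", "CD1")),
  ASN = list(c("ND2", "CG")), GLN = list(c("NE2", "CD"))
)
HB_ACCEPTORS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2")
)

atom_charges <- function(tab) {
  q <- numeric(nrow(tab))
  bb <- PARTIAL_CHARGES$backbone
  for (nm in names(bb)) q[tab$atom_name == nm] <- bb[[nm]]
  for (rt in setdiff(names(PARTIAL_CHARGES), "backbone")) {
    sc <- PARTIAL_CHARGES[[rt]]
    for (nm in names(sc)) {
      q[tab$residue_type == rt & tab$atom_name == nm] <- sc[[nm]]
    }
  }
  q
}

#' Surrogate inter-residue pair energies
#'
#' Computes the three-channel n x n x 3 energy table of a structure:
#' \itemize{
#'   \item electrostatics: screened Coulomb term
#'     `k q_i q_j / (eps(r) r)` with eps(r) = 4r over charged/polar atom
#'     pairs within the cutoff, summed per residue pair;
#'   \item hbond: geometric donor-acceptor score, Gaussian in the
#'     donor-acceptor distance about its optimum with a cosine angular
#'     factor on the antecedent-donor-acceptor angle;
#'   \item solvation: burial-product term from per-atom neighbor counts,
#'     summed over contacting atom pairs.
#' }
#' Each channel is symmetrized and clipped to the configured range; the
#' diagonal is zero. Values depend only on interatomic geometry, so the
#' table is invariant to rigid motions of the structure.
#'
#' @param structure an [all_atom_structure()].
#' @param params a [surrogate_params()].
#' @return an `energy_table`: list with `values` (n x n x 3), `channels`,
#'   `pair_mask`.
#' @export
surrogate_pair_energies <- function(structure, params = surrogate_params()) {
  stopifnot(inherits(structure, "all_atom_structure"))
  tab <- atom_table(structure)
  n <- structure$n_residues
  xyz <- cbind(tab$x, tab$y, tab$z)
  m <- nrow(xyz)
  D <- as.matrix(stats::dist(xyz))
  vals <- array(0, dim = c(n, n, 3L))

  # electrostatics: eps(r) = 4r  ->  k q q / (4 r^2)
  q <- atom_charges(tab)
  ci <- which(q != 0)
  if (length(ci) >= 2L) {
    for (a in ci) for (b in ci) {
      if (a >= b) next
      ra <- tab$residue[a]; rb <- tab$residue[b]
      if (ra == rb) next
      r <- D[a, b]
      if (r > params$elec_cutoff) next
      e <- params$coulomb_k * q[a] * q[b] / (4 * r * r)
      vals[ra, rb, 2L] <- vals[ra, rb, 2L] + e
    }
  }

  # hydrogen bonds: Gaussian distance term x clamped cosine angular factor
  don <- list(); acc <- list()
  for (i in seq_len(m)) {
    rt <- tab$residue_type[i]; nm <- tab$atom_name[i]
    for (dn in c(HB_DONORS$backbone, HB_DONORS[[rt]])) {
      if (nm == dn[1]) {
        ant <- which(tab$residue == tab$residue[i] & tab$atom_name == dn[2])
        if (length(ant) == 1L) don[[length(don) + 1L]] <- c(i, ant)
      }
    }
    if (nm %in% c(HB_ACCEPTORS$backbone, HB_ACCEPTORS[[rt]])) {
      acc[[length(acc) + 1L]] <- i
    }
  }
  for (dpair in don) {
    dA <- dpair[1]; ant <- dpair[2]
    for (aA in unlist(acc)) {
      ra <- tab$residue[dA]; rb <- tab$residue[aA]
      if (ra == rb) next
      r <- D[dA, aA]
      if (r > params$hbond_cutoff) next
      ang <- bond_angle(xyz[ant, ], xyz[dA, ], xyz[aA, ])
      f <- max(0, -cos(deg2rad(ang)))
      e <- -params$hbond_depth *
        exp(-((r - params$hbond_d0)^2) / (2 * params$hbond_sigma^2)) * f
      vals[ra, rb, 1L] <- vals[ra, rb, 1L] + e
    }
  }

  # solvation: burial product over contacting atom pairs
  burial <- rowSums(D < params$solv_radius) - 1L
  cont <- which(D < params$solv_radius & upper.tri(D), arr.ind = TRUE)
  if (nrow(cont) > 0L) {
    for (k in seq_len(nrow(cont))) {
      a <- cont[k, 1]; b <- cont[k, 2]
      ra <- tab$residue[a]; rb <- tab$residue[b]
      if (ra == rb) next
      vals[ra, rb, 3L] <- vals[ra, rb, 3L] +
        params$solv_scale * burial[a] * burial[b]
    }
  }

  # symmetrize (every term was accumulated on one side), clip, zero diag
  for (k in 1:3) {
    vals[, , k] <- vals[, , k] + t(vals[, , k])
    vals[, , k] <- pmax(pmin(vals[, , k], params$clip), -params$clip)
    diag(vals[, , k]) <- 0
  }
  energy_table(vals)
}

#' Construct an energy table object
#' @param values n x n x 3 array, symmetric per channel, zero diagonal.
#' @export
energy_table <- function(values) {
  n <- dim(values)[1]
  stopifnot(length(dim(values)) == 3L, dim(values)[2] == n,
            dim(values)[3] == 3L, all(is.finite(values)))
  for (k in 1:3) {
    if (max(abs(values[, , k] - t(values[, , k]))) > 1e-9) {
      stop("energy table must be symmetric in its residue indices")
    }
  }
  structure(list(values = values, channels = ENERGY_CHANNELS,
                 pair_mask = !diag(n)), class = "energy_table")
}

#' Read a tab-separated inter-residue energy table
#'
#' Records are (i, j, hbond, elec, solv) with 0-based residue indices;
#' unlisted pairs are zero; the table is mirrored to be symmetric.
#' Conflicting duplicate (i,j)/(j,i) records are averaged with a warning.
#'
#' @param path file path.
#' @param n residue count of the target structure.
#' @return an [energy_table()].
#' @export
read_energy_table <- function(path, n) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  vals <- array(0, dim = c(n, n, 3L))
  cnt <- matrix(0L, n, n)
  if (nrow(df) > 0L) {
    if (any(df[[1]] < 0 | df[[1]] >= n | df[[2]] < 0 | df[[2]] >= n)) {
      stop("residue index out of range in energy table")
    }
    for (r in seq_len(nrow(df))) {
      i <- df[r, 1] + 1L; j <- df[r, 2] + 1L
      e <- as.numeric(df[r, 3:5])
      for (k in 1:3) {
        vals[i, j, k] <- vals[i, j, k] + e[k]
        vals[j, i, k] <- vals[j, i, k] + e[k]
      }
      cnt[i, j] <- cnt[i, j] + 1L; cnt[j, i] <- cnt[j, i] + 1L
    }
    if (any(cnt > 1L)) {
      warning("duplicate pair records averaged")
      for (k in 1:3) {
        vals[, , k] <- ifelse(cnt > 0L, vals[, , k] / pmax(cnt, 1L),
                              vals[, , k])
      }
    }
  }
  for (k in 1:3) diag(vals[, , k]) <- 0
  energy_table(vals)
}

#' Write an energy table as tab-separated records
#'
#' Upper-triangle nonzero entries only, 6-decimal precision, with a
#' header line. An all-zero table yields a header-only file.
#'
#' @param table an [energy_table()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_energy_table <- function(table, path) {
  stopifnot(inherits(table, "energy_table"))
  n <- dim(table$values)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("i", "j", ENERGY_CHANNELS), collapse = "\t"), con)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    e <- table$values[i, j, ]
    if (all(e == 0)) next
    writeLines(paste(c(i - 1L, j - 1L, sprintf("%.6f", e)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
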