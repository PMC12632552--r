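#' @name atom37
#' @title The atom-37 heavy-atom template
#'
#' @description
#' Every canonical residue's heavy atoms are laid out in a fixed-width
#' 37-slot template: one slot for every heavy-atom name that occurs across
#' the 20 canonical amino acids (backbone first: N, CA, C, CB, O, then the
#' side-chain names, then OXT). A residue occupies only the slots named by
#' its chemistry; the remaining slots are masked. The layout is a fixed
#' bijection per residue type, which makes per-residue coordinate blocks
#' (n x 37 x 3) and their masks directly comparable across residue types.
NULL

#' Global atom-37 slot names, in canonical order.
#' @export
ATOM37_NAMES <- c(
  "N", "CA", "C", "CB", "O",
  "CG", "CG1", "CG2", "OG", "OG1", "SG",
  "CD", "CD1", "CD2", "ND1", "ND2", "OD1", "OD2", "SD",
  "CE", "CE1", "CE2", "CE3", "NE", "NE1", "NE2", "OE1", "OE2",
  "CH2", "NH1", "NH2", "OH",
  "CZ", "CZ2", "CZ3", "NZ",
  "OXT"
)

#' Canonical three-letter residue codes (alphabetical).
#' @export
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Canonical one-letter residue codes, aligned with [AA3].
#' @export
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")

# Heavy atoms per residue type (no OXT: terminal oxygens are not modelled).
RESIDUE_ATOMS <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2")
)

#' Convert between one- and three-letter residue codes
#'
#' @param x character vector of codes.
#' @return character vector of converted codes.
#' @export
aa1_to_aa3 <- function(x) {
  idx <- match(toupper(x), AA1)
  if (anyNA(idx)) {
    stop("invalid one-letter residue code(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  AA3[idx]
}

#' @rdname aa1_to_aa3
#' @export
aa3_to_aa1 <- function(x) {
  idx <- match(toupper(x), AA3)
  if (anyNA(idx)) {
    stop("invalid three-letter residue code(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  AA1[idx]
}

#' Heavy-atom names of a residue type
#'
#' @param residue_type three-letter code.
#' @return character vector of heavy-atom names in template order.
#' @export
residue_atom_names <- function(residue_type) {
  atoms <- RESIDUE_ATOMS[[toupper(residue_type)]]
  if (is.null(atoms)) stop("unknown residue type: ", residue_type)
  atoms
}

#' Atom-37 slot index of an atom within a residue type
#'
#' Total and injective over each residue type's heavy atoms: every heavy
#' atom of a canonical residue maps to exactly one of the 37 slots.
#'
#' @param residue_type three-letter code.
#' @param atom_name PDB heavy-atom name (e.g. "CA", "OD1").
#' @return integer slot index in 1..37.
#' @export
slot_index <- function(residue_type, atom_name) {
  atoms <- residue_atom_names(residue_type)
  atom_name <- toupper(atom_name)
  if (!all(atom_name %in% atoms)) {
    bad <- setdiff(atom_name, atoms)
    stop("atom(s) ", paste(bad, collapse = ", "), " not part of ",
         residue_type)
  }
  match(atom_name, ATOM37_NAMES)
}

#' Atom-37 occupancy mask row for a residue type
#'
#' @param residue_type three-letter code.
#' @return logical vector of length 37.
#' @export
atom37_mask_row <- function(residue_type) {
  ATOM37_NAMES %in% residue_atom_names(residue_type)
}

#' Chemical element of each atom-37 slot
#'
#' Inferred from the leading character of the atom name (all heavy atoms of
#' the canonical residues are C, N, O or S).
#'
#' @return character vector of length 37 over {"C","N","O","S"}.
#' @export
atom37_elements <- function() {
  substr(ATOM37_NAMES, 1L, 1L)
}
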