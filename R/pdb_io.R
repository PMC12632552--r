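# PDB reading/writing behind the atom-37 data model. Parsing and record
# formatting are delegated to bio3d; this layer resolves altlocs, drops
# hydrogens and waters, maps selenomethionine to methionine, skips other
# non-canonical residues with a warning, and lays coordinates into the
# fixed atom-37 slots.

#' Read a PDB file into an all-atom structure
#'
#' Heavy atoms only (hydrogens and deuteriums dropped); alternate
#' locations resolved to the highest-occupancy copy; selenomethionine is
#' read as methionine (SE -> SD); other non-canonical residues are skipped
#' with a warning. Only the first model of multi-model files is used.
#'
#' @param path PDB file path.
#' @return an [all_atom_structure()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file: ", path, " (",
                             conditionMessage(e), ")")
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" | at$resid == "MSE", , drop = FALSE]
  # selenomethionine -> methionine
  sel <- at$resid == "MSE"
  at$resid[sel] <- "MET"
  at$elety[sel & at$elety == "SE"] <- "SD"
  # heavy atoms only
  elem <- toupper(sub("^\\s+|\\s+$", "", ifelse(is.na(at$elesy) | at$elesy == "",
                                                substr(at$elety, 1, 1),
                                                at$elesy)))
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  # skip non-canonical residues (with one warning listing them)
  bad <- !(at$resid %in% AA3)
  if (any(bad)) {
    warning("skipping non-canonical residue(s): ",
            paste(unique(at$resid[bad]), collapse = ", "))
    at <- at[!bad, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no canonical protein residues found in ", path)
  # altloc: keep highest occupancy per (chain, resno, insert, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    idx[which.max(occ[idx])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  rkeys <- unique(rkey)  # file order
  n <- length(rkeys)
  coords <- array(0, dim = c(n, 37, 3))
  mask <- matrix(FALSE, n, 37)
  res3 <- character(n); chains <- character(n)
  for (i in seq_len(n)) {
    sub <- at[rkey == rkeys[i], , drop = FALSE]
    res3[i] <- sub$resid[1L]
    chains[i] <- if (is.na(sub$chain[1L]) || sub$chain[1L] == "") "A" else sub$chain[1L]
    allowed <- residue_atom_names(res3[i])
    for (k in seq_len(nrow(sub))) {
      nm <- toupper(sub$elety[k])
      if (!nm %in% allowed) next  # OXT, unknown names: ignored
      s <- match(nm, ATOM37_NAMES)
      coords[i, s, ] <- c(sub$x[k], sub$y[k], sub$z[k])
      mask[i, s] <- TRUE
    }
  }
  keep_res <- rowSums(mask) > 0L
  if (!any(keep_res)) stop("no canonical protein residues found in ", path)
  all_atom_structure(res3[keep_res],
                     coords[keep_res, , , drop = FALSE],
                     mask[keep_res, , drop = FALSE],
                     chains[keep_res])
}

#' Write an all-atom structure to a PDB file
#'
#' Standard ATOM records with sequential serial numbers, occupancy 1.00,
#' B-factor 0.00 and the element column filled. Empty chain labels are
#' written as chain "A".
#'
#' @param structure an [all_atom_structure()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "all_atom_structure"))
  tab <- atom_table(structure)
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(cbind(tab$x, tab$y, tab$z))),
      resno = tab$residue,
      resid = tab$residue_type,
      eleno = seq_len(nrow(tab)),
      elety = tab$atom_name,
      chain = ifelse(nzchar(tab$chain), tab$chain, "A"),
      o = rep(1, nrow(tab)),
      b = rep(0, nrow(tab)),
      elesy = tab$element
    )
    TRUE
  }, error = function(e) {
    stop("cannot write PDB file ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
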