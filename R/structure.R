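#' Parse a PDB structure into the internal atom/residue model
#'
#' Reads ATOM/HETATM records (first model only) and returns a
#' \code{pdna_structure}: an atom table plus a residue table with each
#' residue classified as protein, DNA, RNA or other. Hydrogens and waters
#' are excluded; alternate locations are resolved to the highest occupancy
#' (ties: first in file); HETATM amino acids such as selenomethionine are
#' mapped to their parent residue type. Author residue numbering and
#' insertion codes are preserved end-to-end.
#'
#' @param pdb path to a PDB file, or PDB-format text (a single string with
#'   newlines or a character vector of lines).
#' @param id structure identifier stored in the result.
#' @return an object of class \code{pdna_structure} with elements
#'   \code{id}, \code{atoms} (data frame: chain, resno, insert, resid,
#'   elety, element, x, y, z, o, mol, reskey) and \code{residues}
#'   (data frame: reskey, chain, resno, insert, resid, aa1, mol, natoms).
#' @export
#' @examples
#' fx <- make_pseudo_protein(fixture_spec(seed = 1, n_res = 30))
#' s <- parse_structure(fx$pdb)
#' nrow(s$residues)
parse_structure <- function(pdb, id = "structure") {
  path <- pdb_input_path(pdb)
  p <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB input: ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- p$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("structure contains no ATOM/HETATM records")
  }
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$element <- ifelse(is.na(at$elesy) | at$elesy == "",
                       element_from_name(at$elety), toupper(at$elesy))
  # drop hydrogens and waters
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$resid %in% WATER_RES), , drop = FALSE]
  if (nrow(at) == 0) stop("structure is empty after removing hydrogens/waters")
  # altloc: keep the highest-occupancy conformer per atom (ties: first)
  at$alt[is.na(at$alt)] <- ""
  has_alt <- at$alt != ""
  if (any(has_alt)) {
    at$o[is.na(at$o)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(-at$o, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety, element = at$element,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite atom coordinates in input")
  }
  atoms$mol <- molecule_class(atoms$resid)
  atoms$reskey <- res_key(atoms$chain, atoms$resno, atoms$insert)
  res_idx <- !duplicated(atoms$reskey)
  residues <- data.frame(
    reskey = atoms$reskey[res_idx],
    chain = atoms$chain[res_idx],
    resno = atoms$resno[res_idx],
    insert = atoms$insert[res_idx],
    resid = atoms$resid[res_idx],
    mol = atoms$mol[res_idx],
    stringsAsFactors = FALSE
  )
  residues$aa1 <- aa_one(residues$resid)
  residues$natoms <- as.integer(table(atoms$reskey)[residues$reskey])
  out <- list(id = id, atoms = atoms, residues = residues)
  class(out) <- "pdna_structure"
  out
}

pdb_input_path <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    return(pdb)
  }
  lines <- if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  if (!any(grepl("^(ATOM|HETATM)", lines))) {
    stop("PDB input contains no ATOM/HETATM records")
  }
  tmp <- tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  tmp
}

#' @export
print.pdna_structure <- function(x, ...) {
  tab <- table(x$residues$mol)
  cat("pdna_structure '", x$id, "': ", nrow(x$atoms), " atoms, ",
      nrow(x$residues), " residues (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "), chains: ", paste(unique(x$residues$chain), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Subset a structure to selected molecule classes or chains
#'
#' @param struct a \code{pdna_structure}.
#' @param mol molecule classes to keep (e.g. \code{"protein"}); NULL keeps all.
#' @param chains chain identifiers to keep; NULL keeps all.
#' @return a \code{pdna_structure}.
#' @export
subset_structure <- function(struct, mol = NULL, chains = NULL) {
  keep <- rep(TRUE, nrow(struct$atoms))
  if (!is.null(mol)) keep <- keep & struct$atoms$mol %in% mol
  if (!is.null(chains)) keep <- keep & struct$atoms$chain %in% chains
  atoms <- struct$atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0) stop("subset removes every atom")
  residues <- struct$residues[struct$residues$reskey %in% atoms$reskey, ,
                              drop = FALSE]
  out <- list(id = struct$id, atoms = atoms, residues = residues)
  class(out) <- "pdna_structure"
  out
}

atom_xyz <- function(struct) {
  as.matrix(struct$atoms[, c("x", "y", "z")])
}
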