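# Receptor-peptide complex container and PDB I/O.
#
# A ComplexStructure holds one atom table (receptor chains + a single
# peptide chain), covalent inter-residue links (disulfides, staple closure,
# N-C cyclization) and a flag saying whether the peptide termini are free
# (uncapped termini are treated as ionized charged groups). Coordinates are
# in Angstrom; residue numbering is 1-based within each chain; atom naming
# follows PDB v3.

#' Construct a ComplexStructure
#'
#' @param receptor_atoms,peptide_atoms atom data.frames with columns
#'   `chain, resno, resid, is_d, atom, element, x, y, z` (role is filled in)
#' @param inter_bonds data.frame with columns
#'   `chain1, resno1, atom1, chain2, resno2, atom2`, or NULL
#' @param uncapped logical; TRUE if the peptide termini are free and ionized
#' @return object of class `ComplexStructure`
#' @export
new_complex <- function(receptor_atoms, peptide_atoms, inter_bonds = NULL,
                        uncapped = FALSE) {
  if (is.null(peptide_atoms) || nrow(peptide_atoms) == 0) stop("empty peptide")
  receptor_atoms$role <- "receptor"
  peptide_atoms$role <- "peptide"
  cols <- c("role", "chain", "resno", "resid", "is_d", "atom", "element",
            "x", "y", "z")
  for (nm in c("is_d")) {
    if (is.null(receptor_atoms[[nm]])) receptor_atoms[[nm]] <- FALSE
    if (is.null(peptide_atoms[[nm]])) peptide_atoms[[nm]] <- FALSE
  }
  atoms <- rbind(receptor_atoms[, cols], peptide_atoms[, cols])
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  key <- with(atoms, paste(chain, resno, atom))
  if (anyDuplicated(key)) stop("duplicated atom identifiers")
  atoms$charge_class <- charge_class_of(atoms$resid, atoms$atom, atoms$element)
  if (uncapped) {
    pep <- atoms$role == "peptide"
    first <- min(atoms$resno[pep]); last <- max(atoms$resno[pep])
    atoms$charge_class[pep & atoms$resno == first & atoms$atom == "N"] <-
      "charged-group"
    atoms$charge_class[pep & atoms$resno == last &
                         atoms$atom %in% c("O", "OXT")] <- "charged-group"
  }
  if (!is.null(inter_bonds) && nrow(inter_bonds)) {
    k1 <- with(inter_bonds, paste(chain1, resno1, atom1))
    k2 <- with(inter_bonds, paste(chain2, resno2, atom2))
    if (!all(c(k1, k2) %in% key)) stop("inter-residue bond references missing atom")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, inter_bonds = inter_bonds,
                 uncapped = uncapped),
            class = "ComplexStructure")
}

#' @export
print.ComplexStructure <- function(x, ...) {
  a <- x$atoms
  cat("ComplexStructure:",
      sum(a$role == "receptor"), "receptor atoms /",
      sum(a$role == "peptide"), "peptide atoms;",
      length(unique(a$chain[a$role == "receptor"])), "receptor chain(s),",
      length(unique(a$resno[a$role == "peptide"])), "peptide residues\n")
  if (!is.null(x$inter_bonds) && nrow(x$inter_bonds))
    cat("  inter-residue bonds:", nrow(x$inter_bonds), "\n")
  invisible(x)
}

#' Extract the receptor or peptide atoms of a complex
#' @param cs a `ComplexStructure`
#' @return atom data.frame
#' @export
receptor_atoms <- function(cs) cs$atoms[cs$atoms$role == "receptor", , drop = FALSE]

#' @rdname receptor_atoms
#' @export
peptide_atoms <- function(cs) cs$atoms[cs$atoms$role == "peptide", , drop = FALSE]

#' Read a protein-peptide complex from a PDB file
#'
#' Parses the file with bio3d, keeps the highest-occupancy alternate
#' locations, drops waters, and splits the named chains into receptor and
#' peptide. D-amino-acid residue codes (DAL, DPN, ...) are recognized and
#' mapped to their L parameter templates with `is_d = TRUE`.
#'
#' @param path PDB file
#' @param receptor_chains character vector of receptor chain ids
#' @param peptide_chain single peptide chain id
#' @param uncapped passed to [new_complex()]
#' @return a `ComplexStructure`
#' @export
read_complex <- function(path, receptor_chains, peptide_chain,
                         uncapped = FALSE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  need <- c(receptor_chains, peptide_chain)
  missing <- setdiff(need, unique(at$chain))
  if (length(missing)) stop("chain not found: ", paste(missing, collapse = ", "))
  mk <- function(chains) {
    a <- at[at$chain %in% chains, , drop = FALSE]
    dec <- from_pdb_res_code(a$resid)
    el <- trimws(a$elesy)
    bad <- is.na(el) | el == ""
    el[bad] <- substr(trimws(a$elety[bad]), 1, 1)
    out <- data.frame(chain = a$chain, resid = dec$code, is_d = dec$is_d,
                      atom = trimws(a$elety), element = toupper(el),
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    # renumber 1-based within chain, preserving order
    out$resno <- NA_integer_
    for (ch in unique(out$chain)) {
      sel <- out$chain == ch
      out$resno[sel] <- match(a$resno[sel], unique(a$resno[sel]))
    }
    out
  }
  pep <- mk(peptide_chain)
  if (nrow(pep) == 0) stop("empty peptide")
  new_complex(mk(receptor_chains), pep, uncapped = uncapped)
}

#' Write a complex (or atom table) to a PDB file
#'
#' @param x a `ComplexStructure` or an atom data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_complex <- function(x, path) {
  atoms <- if (inherits(x, "ComplexStructure")) x$atoms else x
  if (is.null(atoms$is_d)) atoms$is_d <- FALSE
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$resno,
    resid = pdb_res_code(atoms$resid, atoms$is_d),
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom,
    chain = atoms$chain,
    elesy = atoms$element)
  invisible(path)
}
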