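# Extended peptide sequence notation.
#
# One-letter codes: uppercase = L-amino acid, lowercase = the D enantiomer.
# Bracketed tokens name non-natural residues, e.g. [Cba] (cyclobutylalanine)
# and the olefinic staple residues [S5]/[R8]; a lowercase bracketed token
# ([cba]) is the D form. A trailing "--" marks head-to-tail (N-C)
# cyclization.

aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# PDB v3 codes for common D-amino acids (used on write; both accepted on read)
d_codes <- c(ALA = "DAL", ARG = "DAR", ASN = "DSG", ASP = "DAS", CYS = "DCY",
             GLN = "DGN", GLU = "DGL", HIS = "DHI", ILE = "DIL", LEU = "DLE",
             LYS = "DLY", MET = "MED", PHE = "DPN", PRO = "DPR", SER = "DSN",
             THR = "DTH", TRP = "DTR", TYR = "DTY", VAL = "DVA")

#' Parse the extended peptide sequence notation
#'
#' @param sequence character scalar, e.g. `"LTF[R8]EYWQL[Cba]SAA[S5]AA"` or
#'   `"aAAA"` (leading D-Ala) or `"TSFAEYWNLLSP--"` (N-C cyclized).
#' @return data.frame with columns `code` (three-letter, L form), `is_d`,
#'   plus attributes `cyclic` (logical) and `staple` (indices of the staple
#'   residue pair, if exactly two staple residues are present).
#' @export
parse_peptide_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  cyclic <- grepl("--$", sequence)
  s <- sub("--$", "", sequence)
  codes <- character(0); isd <- logical(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated bracket in sequence")
      tok <- substr(s, i + 1L, i + j - 2L)
      codes <- c(codes, toupper(tok))
      isd <- c(isd, tok == tolower(tok) && tok != toupper(tok))
      i <- i + j
    } else {
      up <- toupper(ch)
      if (!up %in% names(aa1to3)) stop("unknown residue: ", ch)
      codes <- c(codes, aa1to3[[up]])
      isd <- c(isd, ch %in% letters)
      i <- i + 1L
    }
  }
  bad <- setdiff(codes, known_residues())
  if (length(bad)) stop("unknown residue: ", paste(bad, collapse = ", "))
  out <- data.frame(code = codes, is_d = isd, stringsAsFactors = FALSE)
  attr(out, "cyclic") <- cyclic
  st <- which(codes %in% c("S5", "R8"))
  attr(out, "staple") <- if (length(st) == 2L) st else integer(0)
  out
}

# residue code as written to PDB records
pdb_res_code <- function(code, is_d) {
  ifelse(is_d & code %in% names(d_codes), d_codes[code], code)
}

# inverse mapping on read
from_pdb_res_code <- function(code) {
  code <- toupper(code)
  is_d <- code %in% d_codes
  base <- code
  base[is_d] <- names(d_codes)[match(code[is_d], d_codes)]
  data.frame(code = base, is_d = is_d, stringsAsFactors = FALSE)
}
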