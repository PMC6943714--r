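# Internal-coordinate peptide construction.
#
# Backbone (N, CA, C, O) plus C-beta are built from template bond lengths
# and angles by sequential torsion placement; side chains beyond C-beta are
# not generated (they enter via PDB input or toy construction). D-residues
# are built with the C-beta improper torsion negated, i.e. exact mirror
# side-chain chirality.

.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.5,
  # torsion C(i)-N(i)-CA(i)-CB(i) giving L chirality (negated for D);
  # checked against the positive N-CA-C-CB improper of L residues in
  # experimental structures
  t_cb_l = -122.6
)

#' Build peptide coordinates from backbone torsions
#'
#' Constructs N/CA/C/O/CB coordinates for a peptide at the given phi/psi
#' (and omega) torsions, with fixed template bond lengths and angles.
#'
#' @param residues data.frame from [parse_peptide_sequence()], or a sequence
#'   string which is parsed first
#' @param phi,psi numeric vectors (degrees), recycled to the peptide length
#' @param omega peptide-bond torsion, degrees (default 180, trans)
#' @return atom data.frame (chain "B", role "peptide") with columns
#'   `role, chain, resno, resid, is_d, atom, element, x, y, z`
#' @export
build_peptide <- function(residues, phi = -57, psi = -47, omega = 180) {
  if (is.character(residues)) residues <- parse_peptide_sequence(residues)
  b <- build_peptide_xyz(residues, phi, psi, omega)
  data.frame(
    role = "peptide", chain = "B", resno = b$resno,
    resid = residues$code[b$resno], is_d = residues$is_d[b$resno],
    atom = b$atom, element = substr(b$atom, 1, 1),
    x = b$xyz[, 1], y = b$xyz[, 2], z = b$xyz[, 3], stringsAsFactors = FALSE)
}

# coordinate-only builder (hot path for the samplers): returns the xyz
# matrix plus the atom-name/residue-index layout, which is fixed for a
# given residue table
build_peptide_xyz <- function(residues, phi = -57, psi = -47, omega = 180) {
  n <- nrow(residues)
  stopifnot(n >= 1)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  has_cb <- residues$code != "GLY"
  natom <- sum(4L + has_cb)
  xyz <- matrix(0, natom, 3)
  atom <- character(natom); resno <- integer(natom)
  dummy <- c(0, 1, 0)
  N <- c(0, 0, 0)
  CA <- c(.bb$b_n_ca, 0, 0)
  C <- place_atom(dummy, N, CA, .bb$b_ca_c, .bb$a_n_ca_c, phi[1])
  k <- 0L
  put <- function(nm, p, i) {
    k <<- k + 1L
    xyz[k, ] <<- p; atom[k] <<- nm; resno[k] <<- i
  }
  for (i in seq_len(n)) {
    put("N", N, i); put("CA", CA, i); put("C", C, i)
    put("O", place_atom(N, CA, C, .bb$b_c_o, .bb$a_ca_c_o, psi[i] + 180), i)
    if (has_cb[i]) {
      tcb <- if (residues$is_d[i]) -.bb$t_cb_l else .bb$t_cb_l
      put("CB", place_atom(C, N, CA, .bb$b_ca_cb, .bb$a_n_ca_cb, tcb), i)
    }
    if (i < n) {
      N2 <- place_atom(N, CA, C, .bb$b_c_n, .bb$a_ca_c_n, psi[i])
      CA2 <- place_atom(CA, C, N2, .bb$b_n_ca, .bb$a_c_n_ca, omega[i])
      C2 <- place_atom(C, N2, CA2, .bb$b_ca_c, .bb$a_n_ca_c, phi[i + 1])
      N <- N2; CA <- CA2; C <- C2
    }
  }
  list(xyz = xyz, atom = atom, resno = resno)
}

#' Build an ideal helical peptide
#'
#' Convenience wrapper over [build_peptide()] at fixed helical torsions
#' (defaults: alpha-helix, phi = -57, psi = -47).
#'
#' @inheritParams build_peptide
#' @param sequence extended-notation sequence string
#' @return atom data.frame as in [build_peptide()]
#' @export
build_ideal_helix <- function(sequence, phi = -57, psi = -47) {
  build_peptide(sequence, phi = phi, psi = psi)
}

# extract the torsions implied by a built peptide (used in tests and by the
# sampler's round-trip contract)
peptide_torsions <- function(atoms) {
  resno <- sort(unique(atoms$resno))
  get <- function(i, nm) {
    r <- atoms[atoms$resno == i & atoms$atom == nm, c("x", "y", "z")]
    if (nrow(r) != 1) return(NULL)
    as.numeric(r)
  }
  n <- length(resno)
  phi <- psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    i <- resno[k]
    if (k > 1) {
      p <- get(resno[k - 1], "C")
      phi[k] <- dihedral(p, get(i, "N"), get(i, "CA"), get(i, "C"))
    }
    if (k < n) {
      q <- get(resno[k + 1], "N")
      psi[k] <- dihedral(get(i, "N"), get(i, "CA"), get(i, "C"), q)
    }
  }
  cbind(phi = phi, psi = psi)
}
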