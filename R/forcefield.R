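# Simplified heavy-atom force field.
#
# Van der Waals: 12-6 Lennard-Jones with Amber-style r_min/epsilon per atom
# type (Lorentz-Berthelot combination: r_min additive, epsilon geometric).
# Electrostatics: Coulomb with a distance-dependent dielectric eps(d) = 4d,
# i.e. pair energy k q_i q_j / (4 d^2), k = 332.0636 kcal A / (mol e^2).
# Solvation: Gaussian-exclusion continuum term (Lazaridis-Karplus style)
# over heavy atoms. Nonpolar solvation: 0.65 kcal/(mol A^2) times SASA.
# Charges are a bundled static per-residue-template table with implicit
# hydrogens folded into their heavy atoms; the table is data, not code, and
# is shipped as versioned CSV.

#' Force-field parameter set
#'
#' @param sasa_scale nonpolar surface-area-to-energy scale, kcal/(mol A^2)
#' @param coulomb_constant electrostatic constant, kcal A/(mol e^2)
#' @return list of class `ForceFieldParams`
#' @export
ff_params <- function(sasa_scale = 0.65, coulomb_constant = 332.0636) {
  lj <- lj_param_table(); solv <- solvation_param_table()
  structure(list(
    lj = setNames(split(lj[, c("rmin_half", "epsilon")], seq_len(nrow(lj))),
                  lj$type),
    solv = setNames(split(solv[, c("dg_ref", "volume", "lambda")],
                          seq_len(nrow(solv))), solv$type),
    coulomb_constant = coulomb_constant,
    sasa_scale = sasa_scale), class = "ForceFieldParams")
}

# per-atom parameter assignment: lj type, solvation type, charge
assign_ff <- function(atoms, params = ff_params(), neutralize = FALSE) {
  tab <- residue_template_table()
  key <- paste(atoms$resid, atoms$atom)
  m <- match(key, paste(tab$res, tab$atom))
  bbrows <- which(tab$res == "*")
  bb <- match(atoms$atom, tab$atom[bbrows])
  use_bb <- is.na(m) & !is.na(bb)
  m[use_bb] <- bbrows[bb[use_bb]]
  el_default <- c(C = "CT", N = "N", O = "O", S = "S", H = "H")
  el_solv <- c(C = "CH2E", N = "NH1", O = "O", S = "S", H = "H")
  lj_type <- ifelse(is.na(m), el_default[atoms$element], tab$lj_type[m])
  solv_type <- ifelse(is.na(m), el_solv[atoms$element], tab$solv_type[m])
  charge <- ifelse(is.na(m), 0, tab$charge[m])
  if (any(is.na(lj_type)))
    stop("unparameterized atom type: ",
         paste(unique(atoms$element[is.na(lj_type)]), collapse = ", "))
  if (neutralize && !is.null(atoms$charge_class))
    charge[atoms$charge_class == "charged-group"] <- 0
  rh <- vapply(params$lj[lj_type], function(p) p$rmin_half, numeric(1))
  ep <- vapply(params$lj[lj_type], function(p) p$epsilon, numeric(1))
  dg <- vapply(params$solv[solv_type], function(p) p$dg_ref, numeric(1))
  vol <- vapply(params$solv[solv_type], function(p) p$volume, numeric(1))
  lam <- vapply(params$solv[solv_type], function(p) p$lambda, numeric(1))
  data.frame(lj_type = lj_type, solv_type = solv_type, charge = charge,
             rmin_half = rh, epsilon = ep, dg_ref = dg, volume = vol,
             lambda = lam, radius = unname(sasa_radii[atoms$element]),
             stringsAsFactors = FALSE)
}

# bond list (pairs of row indices) from residue templates + peptide bonds +
# explicit inter-residue bonds; peptide bond inferred only when the C-N
# distance is chemically sensible (< 1.8 A)
bond_list <- function(atoms, inter_bonds = NULL) {
  tab <- residue_template_table()
  n <- nrow(atoms)
  key <- function(chain, resno, atom) paste(chain, resno, atom)
  idx <- setNames(seq_len(n), key(atoms$chain, atoms$resno, atoms$atom))
  bonds <- list()
  for (i in seq_len(n)) {
    tmpl <- tab[(tab$res == atoms$resid[i] | tab$res == "*") &
                  tab$atom == atoms$atom[i], ]
    if (!nrow(tmpl)) next
    pn <- strsplit(tmpl$parents[1], ";", fixed = TRUE)[[1]]
    for (p in pn) {
      j <- idx[key(atoms$chain[i], atoms$resno[i], p)]
      if (!is.na(j)) bonds[[length(bonds) + 1L]] <- sort(c(i, j))
    }
  }
  # peptide bonds within each chain
  for (ch in unique(atoms$chain)) {
    rs <- sort(unique(atoms$resno[atoms$chain == ch]))
    for (k in seq_along(rs)[-1]) {
      i <- idx[key(ch, rs[k - 1], "C")]; j <- idx[key(ch, rs[k], "N")]
      if (!is.na(i) && !is.na(j)) {
        d2 <- sum((as.numeric(atoms[i, c("x", "y", "z")]) -
                     as.numeric(atoms[j, c("x", "y", "z")]))^2)
        if (d2 < 1.8^2) bonds[[length(bonds) + 1L]] <- sort(c(i, j))
      }
    }
  }
  if (!is.null(inter_bonds) && nrow(inter_bonds)) {
    for (r in seq_len(nrow(inter_bonds))) {
      i <- idx[key(inter_bonds$chain1[r], inter_bonds$resno1[r],
                   inter_bonds$atom1[r])]
      j <- idx[key(inter_bonds$chain2[r], inter_bonds$resno2[r],
                   inter_bonds$atom2[r])]
      if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1L]] <- sort(c(i, j))
    }
  }
  if (!length(bonds)) return(matrix(integer(0), 0, 2))
  unique(do.call(rbind, bonds))
}

# nonbonded pair list with 1-2/1-3 exclusion and 1-4 scaling 0.5
pair_list <- function(n, bonds) {
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), scale = numeric(0)))
  adj <- vector("list", n)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  # breadth-limited bond distance (up to 3)
  sep <- function(i) {
    d <- rep(99L, n); d[i] <- 0L; frontier <- i
    for (s in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[nxt] > s]
      if (!length(nxt)) break
      d[nxt] <- s; frontier <- nxt
    }
    d
  }
  ii <- jj <- integer(0); sc <- numeric(0)
  for (i in seq_len(n - 1)) {
    d <- sep(i)
    j <- (i + 1):n
    keep <- d[j] >= 3L
    j <- j[keep]
    if (!length(j)) next
    ii <- c(ii, rep(i, length(j))); jj <- c(jj, j)
    sc <- c(sc, ifelse(d[j] == 3L, 0.5, 1.0))
  }
  data.frame(i = ii, j = jj, scale = sc)
}
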