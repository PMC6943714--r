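# Interface descriptors: burial, hydrogen bonds, salt bridges, packing
# surrogates.
#
# The four empirical descriptors are: hydrophobic burial (interface-buried
# solvent-accessible area of C/S atoms), charged-group burial (same over N/O
# atoms of Asp/Glu/Lys/Arg side chains and ionized free termini), the count
# of conventional hydrogen bonds across the interface, and the net number
# of salt bridges (favorable opposite-charge group contacts minus repulsive
# like-charge contacts). "Conventional" hydrogen bonds here exclude pairs
# where both atoms belong to charged groups - those contacts are the salt
# bridges and are not double counted.

# join atom table with per-atom template metadata (donor/acceptor/parents)
atom_metadata <- function(atoms) {
  tab <- residue_template_table()
  key <- paste(atoms$resid, atoms$atom)
  m <- match(key, paste(tab$res, tab$atom))
  bb <- match(atoms$atom, tab$atom[tab$res == "*"])
  bbrows <- which(tab$res == "*")
  use_bb <- is.na(m) & !is.na(bb)
  m[use_bb] <- bbrows[bb[use_bb]]
  donor <- ifelse(is.na(m), 0L, tab$donor[m])
  donor[atoms$resid == "PRO" & atoms$atom == "N"] <- 0L
  acceptor <- ifelse(is.na(m), as.integer(atoms$element == "O"), tab$acceptor[m])
  parents <- ifelse(is.na(m), "", tab$parents[m])
  data.frame(donor = donor, acceptor = acceptor, parents = parents,
             stringsAsFactors = FALSE)
}

# idealized donor-hydrogen direction: opposite the mean direction of the
# donor's bonded heavy neighbors (within-residue template neighbors plus a
# preceding-residue carbonyl carbon if one is bonded)
.donor_h_dir <- function(atoms, idx, meta) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dirs <- matrix(NA_real_, length(idx), 3)
  for (k in seq_along(idx)) {
    i <- idx[k]
    pn <- strsplit(meta$parents[i], ";", fixed = TRUE)[[1]]
    sel <- which(atoms$chain == atoms$chain[i] & atoms$resno == atoms$resno[i] &
                   atoms$atom %in% pn)
    if (atoms$atom[i] == "N") { # possible peptide bond to previous residue
      prev <- which(atoms$chain == atoms$chain[i] &
                      atoms$resno == atoms$resno[i] - 1 & atoms$atom == "C")
      if (length(prev) == 1 &&
          sum((xyz[prev, ] - xyz[i, ])^2) < 1.8^2) sel <- c(sel, prev)
    }
    if (!length(sel)) next
    v <- colSums(matrix(xyz[sel, ] - rep(xyz[i, ], each = length(sel)),
                        ncol = 3))
    nv <- vnorm(v)
    if (nv > 1e-8) dirs[k, ] <- -v / nv
  }
  dirs
}

#' Per-atom interface burial
#'
#' dSASA(atom) = SASA in the isolated component - SASA in the complex.
#'
#' @param cs a `ComplexStructure`
#' @param probe,n_points passed to [compute_sasa()]
#' @return list with `dsasa` (per atom, complex order), `buried_hydrophobic`
#'   and `buried_charged` (class-summed areas, A^2), `buried_SA` (total
#'   interface buried area over all atoms), and `n_buried_hydrophobic`
#'   (atoms with dSASA > 1 A^2)
#' @export
compute_burial <- function(cs, probe = 1.4, n_points = 960) {
  a <- cs$atoms
  full <- compute_sasa(a, probe, n_points)$per_atom_area
  iso <- numeric(nrow(a))
  rec <- a$role == "receptor"
  iso[rec] <- compute_sasa(a[rec, ], probe, n_points)$per_atom_area
  iso[!rec] <- compute_sasa(a[!rec, ], probe, n_points)$per_atom_area
  dsasa <- pmax(iso - full, 0)
  hyd <- a$charge_class == "hydrophobic"
  chg <- a$charge_class == "charged-group"
  list(dsasa = dsasa,
       buried_hydrophobic = sum(dsasa[hyd]),
       buried_charged = sum(dsasa[chg]),
       buried_SA = sum(dsasa),
       n_buried_hydrophobic = sum(hyd & !rec & dsasa > 1))
}

#' Count conventional hydrogen bonds across the interface
#'
#' Donor and acceptor roles come from the residue templates; donor hydrogen
#' positions are inferred from heavy-atom connectivity (ideal H along the
#' direction opposite the donor's bonded neighbors). A bond requires
#' donor...acceptor distance <= `d_max` and D-H...A angle >= `angle_min`;
#' each donor is paired with at most its best-geometry acceptor. Pairs in
#' which both atoms belong to charged groups are counted as salt bridges
#' instead (see [count_salt_bridges()]).
#'
#' @param cs a `ComplexStructure`
#' @param d_max donor-acceptor heavy-atom cutoff, Angstrom
#' @param angle_min minimum D-H...A angle, degrees
#' @return integer hydrogen-bond count `XHB`
#' @export
count_hbonds <- function(cs, d_max = 3.5, angle_min = 120) {
  a <- cs$atoms
  meta <- atom_metadata(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  count <- 0L
  for (side in c("peptide", "receptor")) {
    don <- which(a$role == side & meta$donor > 0)
    acc <- which(a$role != side & meta$acceptor > 0)
    if (!length(don) || !length(acc)) next
    hdir <- .donor_h_dir(a, don, meta)
    for (k in seq_along(don)) {
      i <- don[k]
      if (any(is.na(hdir[k, ]))) next
      dv <- xyz[acc, , drop = FALSE] -
        matrix(xyz[i, ], length(acc), 3, byrow = TRUE)
      dd <- sqrt(rowSums(dv^2))
      h <- xyz[i, ] + hdir[k, ] # 1.0 A ideal H
      av <- xyz[acc, , drop = FALSE] - matrix(h, length(acc), 3, byrow = TRUE)
      # angle at H between H->D and H->A
      cosang <- ((-hdir[k, 1]) * av[, 1] + (-hdir[k, 2]) * av[, 2] +
                   (-hdir[k, 3]) * av[, 3]) / sqrt(rowSums(av^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      salt_pair <- a$charge_class[i] == "charged-group" &
        a$charge_class[acc] == "charged-group"
      ok <- dd <= d_max & ang >= angle_min & !salt_pair
      if (any(ok)) count <- count + 1L # best acceptor only, one per donor
    }
  }
  count
}

# charged side-chain / terminus groups: list of atom index vectors + signs
.charged_groups <- function(cs) {
  a <- cs$atoms
  grp <- list(); sgn <- integer(0); role <- character(0)
  idx <- which(a$charge_class == "charged-group")
  if (!length(idx)) return(list(groups = grp, sign = sgn, role = role))
  keys <- paste(a$chain[idx], a$resno[idx],
                ifelse(a$atom[idx] %in% c("N", "O", "OXT"), a$atom[idx] %in% "N",
                       "side"))
  for (k in unique(keys)) {
    ii <- idx[keys == k]
    el <- a$element[ii]
    grp[[length(grp) + 1L]] <- ii
    sgn <- c(sgn, if (all(el == "N")) 1L else -1L)
    role <- c(role, a$role[ii[1]])
  }
  list(groups = grp, sign = sgn, role = role)
}

#' Net salt-bridge count across the interface
#'
#' Charged groups (Asp/Glu carboxylates, Lys ammonium, Arg guanidinium,
#' ionized free termini) are paired across the interface when any of their
#' member N/O atoms lie within `d_max`. The net count is favorable
#' (opposite-charge) pairs minus repulsive (like-charge) pairs.
#'
#' @param cs a `ComplexStructure`
#' @param d_max atom-atom cutoff, Angstrom
#' @return integer net salt-bridge count `XSB` (may be negative)
#' @export
count_salt_bridges <- function(cs, d_max = 4.0) {
  g <- .charged_groups(cs)
  if (length(g$groups) < 2) return(0L)
  xyz <- as.matrix(cs$atoms[, c("x", "y", "z")])
  pep <- which(g$role == "peptide"); rec <- which(g$role == "receptor")
  net <- 0L
  for (i in pep) for (j in rec) {
    di <- xyz[g$groups[[i]], , drop = FALSE]
    dj <- xyz[g$groups[[j]], , drop = FALSE]
    mind2 <- min(outer(rowSums(di^2), rowSums(dj^2), "+") - 2 * di %*% t(dj))
    if (mind2 <= d_max^2)
      net <- net + if (g$sign[i] * g$sign[j] < 0) 1L else -1L
  }
  net
}

#' Compute the four empirical interface descriptors
#'
#' @param cs a `ComplexStructure`
#' @param conversion area-to-energy conversion for the burial descriptors,
#'   kcal/(mol A^2). The physical scale of the burial terms is not uniquely
#'   defined by their published description; the default is a common
#'   hydrophobic-effect scale and is fully configurable.
#' @param hb_d_max,hb_angle_min hydrogen-bond criteria
#' @param sb_d_max salt-bridge cutoff
#' @param probe,n_points SASA settings
#' @param skip_burial if TRUE, skip the (relatively costly) SASA burial and
#'   return zero burial terms; used when only the counts are needed
#' @return list of class `InterfaceDescriptors` with `dXH`, `dXC` (kcal/mol),
#'   `XHB`, `XSB` (counts), `buried_SA` (A^2) and the raw burial areas
#' @export
compute_descriptors <- function(cs, conversion = 0.025, hb_d_max = 3.5,
                                hb_angle_min = 120, sb_d_max = 4.0,
                                probe = 1.4, n_points = 960,
                                skip_burial = FALSE) {
  if (skip_burial) {
    bur <- list(buried_hydrophobic = 0, buried_charged = 0, buried_SA = 0,
                n_buried_hydrophobic = 0L)
  } else {
    bur <- compute_burial(cs, probe, n_points)
  }
  structure(list(
    dXH = conversion * bur$buried_hydrophobic,
    dXC = conversion * bur$buried_charged,
    XHB = count_hbonds(cs, hb_d_max, hb_angle_min),
    XSB = count_salt_bridges(cs, sb_d_max),
    buried_SA = bur$buried_SA,
    raw = list(buried_hydrophobic_area = bur$buried_hydrophobic,
               buried_charged_area = bur$buried_charged,
               n_buried_hydrophobic = bur$n_buried_hydrophobic),
    conversion = conversion), class = "InterfaceDescriptors")
}

#' @export
print.InterfaceDescriptors <- function(x, ...) {
  cat(sprintf(
    "InterfaceDescriptors: dXH=%.3f dXC=%.3f (kcal/mol), XHB=%d XSB=%d, buried SA=%.1f A^2\n",
    x$dXH, x$dXC, x$XHB, x$XSB, x$buried_SA))
  invisible(x)
}

#' Packing-normality surrogate metrics
#'
#' Simple bundled stand-ins for knowledge-based packing quality Z-scores:
#' dihedral normality from a coarse Ramachandran frequency map of the
#' peptide backbone, and 1D/3D packing normality from interface
#' atom-contact-count Z-scores against a Poisson-like reference. These feed
#' the fixed-weight combiner ([packing_score()]); they are surrogates, not a
#' reimplementation of any published knowledge-based potential.
#'
#' @param cs a `ComplexStructure`
#' @param contact_cutoff contact distance for packing counts, Angstrom
#' @return list of class `PackingMetrics` with `dihedral_normality`,
#'   `packing1d_normality`, `packing3d_normality`
#' @export
packing_metrics <- function(cs, contact_cutoff = 4.5) {
  pep <- peptide_atoms(cs)
  tor <- tryCatch(peptide_torsions(pep), error = function(e) NULL)
  dihedral_z <- 0
  if (!is.null(tor)) {
    phi <- tor[, "phi"]; psi <- tor[, "psi"]
    ok <- !is.na(phi) & !is.na(psi)
    if (any(ok)) {
      # fraction in broadly allowed regions, mapped to a z-like score
      inreg <- (phi[ok] < 0) | (abs(phi[ok]) > 150)
      dihedral_z <- 2 * mean(inreg) - 1
    }
  }
  rxyz <- as.matrix(receptor_atoms(cs)[, c("x", "y", "z")])
  pxyz <- as.matrix(pep[, c("x", "y", "z")])
  cnt <- 0
  if (nrow(rxyz) && nrow(pxyz)) {
    d2 <- outer(rowSums(pxyz^2), rowSums(rxyz^2), "+") - 2 * pxyz %*% t(rxyz)
    cnt <- rowSums(d2 <= contact_cutoff^2)
  }
  lambda <- 3 # reference mean contacts per interface atom
  z <- (mean(cnt) - lambda) / sqrt(lambda / max(1, length(cnt)))
  structure(list(dihedral_normality = dihedral_z,
                 packing1d_normality = z,
                 packing3d_normality = z * 0.8),
            class = "PackingMetrics")
}
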