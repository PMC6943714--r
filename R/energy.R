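# Energy evaluation: pairwise nonbonded terms, Gaussian-exclusion implicit
# solvation, nonpolar SASA term, and the component-sum breakdown. The total
# is always the plain sum of the components - no reweighting.

.pair_vdw_coul <- function(xyz, ff, pairs, coulomb_constant) {
  if (!nrow(pairs)) return(c(vdw = 0, coulomb = 0))
  dx <- xyz[pairs$i, , drop = FALSE] - xyz[pairs$j, , drop = FALSE]
  r2 <- pmax(rowSums(dx^2), 0.01)
  rmin <- ff$rmin_half[pairs$i] + ff$rmin_half[pairs$j]
  eps <- sqrt(ff$epsilon[pairs$i] * ff$epsilon[pairs$j])
  s6 <- (rmin^2 / r2)^3
  vdw <- sum(pairs$scale * eps * (s6^2 - 2 * s6))
  coul <- sum(pairs$scale * coulomb_constant *
                ff$charge[pairs$i] * ff$charge[pairs$j] / (4 * r2))
  c(vdw = vdw, coulomb = coul)
}

#' Nonbonded energy between (or within) atom groups
#'
#' For two distinct groups, all cross pairs are evaluated and intra-group
#' pairs are excluded. For a single group (`group_b = NULL`) the internal
#' energy is computed with 1-2/1-3 exclusions and 1-4 scaling 0.5 derived
#' from template connectivity.
#'
#' @param group_a,group_b atom data.frames; `group_b = NULL` for internal
#'   energy of `group_a`
#' @param params a [ff_params()]
#' @param neutralize zero the charges of charged groups
#' @param inter_bonds passed to the bond-graph construction (single-group
#'   mode)
#' @return list of class `EnergyBreakdown`: `vdw`, `coulomb`, `solvation`,
#'   `nonpolar_sasa`, `total` (kcal/mol; solvation terms are zero here and
#'   filled by the callers that request them)
#' @export
nonbonded_energy <- function(group_a, group_b = NULL, params = ff_params(),
                             neutralize = FALSE, inter_bonds = NULL) {
  if (is.null(group_b)) {
    ff <- assign_ff(group_a, params, neutralize)
    bonds <- bond_list(group_a, inter_bonds)
    pairs <- pair_list(nrow(group_a), bonds)
    xyz <- as.matrix(group_a[, c("x", "y", "z")])
    e <- .pair_vdw_coul(xyz, ff, pairs, params$coulomb_constant)
  } else {
    na <- nrow(group_a); nb <- nrow(group_b)
    cols <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
    if (!is.null(group_a$charge_class) && !is.null(group_b$charge_class))
      cols <- c(cols, "charge_class")
    both <- rbind(group_a[, cols], group_b[, cols])
    ff <- assign_ff(both, params, neutralize)
    pairs <- expand.grid(i = seq_len(na), j = na + seq_len(nb))
    pairs$scale <- 1
    xyz <- as.matrix(both[, c("x", "y", "z")])
    e <- .pair_vdw_coul(xyz, ff, pairs, params$coulomb_constant)
  }
  energy_breakdown(vdw = e[["vdw"]], coulomb = e[["coulomb"]])
}

#' Assemble an energy breakdown whose total is the exact component sum
#' @param vdw,coulomb,solvation,nonpolar_sasa components, kcal/mol
#' @return list of class `EnergyBreakdown`
#' @export
energy_breakdown <- function(vdw = 0, coulomb = 0, solvation = 0,
                             nonpolar_sasa = 0) {
  structure(list(vdw = vdw, coulomb = coulomb, solvation = solvation,
                 nonpolar_sasa = nonpolar_sasa,
                 total = vdw + coulomb + solvation + nonpolar_sasa),
            class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf(
    "EnergyBreakdown (kcal/mol): vdw %.3f + coulomb %.3f + solvation %.3f + nonpolar %.3f = %.3f\n",
    x$vdw, x$coulomb, x$solvation, x$nonpolar_sasa, x$total))
  invisible(x)
}

#' Gaussian-exclusion implicit solvation energy
#'
#' Each fully exposed atom contributes exactly its reference solvation free
#' energy; neighboring atoms subtract Gaussian-weighted exclusion terms
#' proportional to their volumes. Pairs beyond `cutoff` are ignored.
#'
#' @param atoms atom data.frame or `ComplexStructure`
#' @param params a [ff_params()]
#' @param cutoff pair cutoff, Angstrom
#' @return solvation free energy, kcal/mol
#' @export
solvation_energy <- function(atoms, params = ff_params(), cutoff = 9) {
  if (inherits(atoms, "ComplexStructure")) atoms <- atoms$atoms
  ff <- assign_ff(atoms, params)
  n <- nrow(atoms)
  if (n == 1) return(ff$dg_ref)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  excl <- 0
  pre <- 2 * ff$dg_ref / (4 * pi * sqrt(pi) * ff$lambda)
  for (i in seq_len(n)) {
    j <- which(d[i, ] > 0 & d[i, ] < cutoff)
    if (!length(j)) next
    r <- d[i, j]
    x <- (r - ff$radius[i]) / ff$lambda[i]
    excl <- excl + sum(pre[i] * exp(-x^2) / r^2 * ff$volume[j])
  }
  sum(ff$dg_ref) - excl
}

# full minimization/scoring energy of one atom set: geometry restraints
# (added by the minimizer), nonbonded, and optionally solvation
.group_energy <- function(atoms, params, neutralize = FALSE,
                          solvated = FALSE, inter_bonds = NULL,
                          n_points = 240) {
  nb <- nonbonded_energy(atoms, NULL, params, neutralize, inter_bonds)
  solv <- 0; np <- 0
  if (solvated) {
    solv <- solvation_energy(atoms, params)
    np <- params$sasa_scale * compute_sasa(atoms, n_points = n_points)$total
  }
  energy_breakdown(nb$vdw, nb$coulomb, solv, np)
}

#' Rigid-body binding energy of a complex, four flavors
#'
#' `simple`: E(complex) - E(protein) - E(peptide) with both components in
#' exactly their in-complex conformations. `strain`: same, but the extracted
#' peptide is energy-minimized first, so a strained bound conformation pays
#' a non-negative penalty. `neutralized`: the simple flavor with all charged
#' side-chain groups (and ionized termini) set to neutral charges.
#' `solvated`: the simple flavor with the implicit-solvation term and the
#' nonpolar surface term (0.65 kcal/(mol A^2) times SASA) included in each
#' Energy(). The solvated flavor substitutes the Gaussian-exclusion polar
#' term for a Poisson-Boltzmann solver while keeping the published nonpolar
#' surface scale; this is a deliberate simplification, stated prominently.
#'
#' @param cs a `ComplexStructure`
#' @param flavor one of `"simple"`, `"strain"`, `"neutralized"`, `"solvated"`
#' @param params a [ff_params()]
#' @param minimize_control settings for the strain-flavor minimization
#' @return binding energy, kcal/mol
#' @export
binding_energy <- function(cs, flavor = c("simple", "strain", "neutralized",
                                          "solvated"),
                           params = ff_params(),
                           minimize_control = list(max_iter = 200)) {
  flavor <- match.arg(flavor)
  rec <- receptor_atoms(cs); pep <- peptide_atoms(cs)
  neutral <- flavor == "neutralized"
  solv <- flavor == "solvated"
  e_cplx <- .group_energy(cs$atoms, params, neutral, solv, cs$inter_bonds)$total
  e_rec <- .group_energy(rec, params, neutral, solv)$total
  if (flavor == "strain") {
    mn <- minimize_atoms(pep, movable = rep(TRUE, nrow(pep)), params = params,
                         max_iter = minimize_control$max_iter,
                         inter_bonds = cs$inter_bonds)
    e_pep <- .group_energy(mn$atoms, params, FALSE, FALSE, cs$inter_bonds)$total
  } else {
    e_pep <- .group_energy(pep, params, neutral, solv, cs$inter_bonds)$total
  }
  e_cplx - e_rec - e_pep
}
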