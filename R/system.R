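# Precomputed energy "systems": topology-dependent quantities (force-field
# assignment, exclusion-aware pair lists, solvation prefactors) are built
# once per molecule, after which an energy evaluation is pure vectorized
# arithmetic over coordinates. The samplers evaluate energies thousands of
# times on a fixed topology, so this is the difference between seconds and
# hours.

# system for one molecule given its atom table (order must stay fixed)
pep_system <- function(atoms, params = ff_params(), inter_bonds = NULL,
                       neutralize = FALSE) {
  ff <- assign_ff(atoms, params, neutralize)
  n <- nrow(atoms)
  bonds <- bond_list(atoms, inter_bonds)
  p <- pair_list(n, bonds)
  nb <- list(i = p$i, j = p$j,
             rmin2 = (ff$rmin_half[p$i] + ff$rmin_half[p$j])^2,
             eps = p$scale * sqrt(ff$epsilon[p$i] * ff$epsilon[p$j]),
             qq = p$scale * params$coulomb_constant *
               ff$charge[p$i] * ff$charge[p$j] / 4)
  # all unordered pairs for the solvation exclusion sum
  if (n >= 2) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pre <- 2 * ff$dg_ref / (4 * pi * sqrt(pi) * ff$lambda)
    solv <- list(i = idx[, 1], j = idx[, 2],
                 a_ij = pre[idx[, 1]] * ff$volume[idx[, 2]],
                 a_ji = pre[idx[, 2]] * ff$volume[idx[, 1]],
                 r_i = ff$radius[idx[, 1]], r_j = ff$radius[idx[, 2]],
                 l_i = ff$lambda[idx[, 1]], l_j = ff$lambda[idx[, 2]])
  } else solv <- NULL
  list(n = n, ff = ff, nb = nb, solv = solv, dg_ref_sum = sum(ff$dg_ref))
}

# internal energy (vdW + Coulomb/4d + Gaussian-exclusion solvation)
sys_energy <- function(sys, xyz, cutoff = 9) {
  e <- sys$dg_ref_sum
  nb <- sys$nb
  if (length(nb$i)) {
    dx <- xyz[nb$i, 1] - xyz[nb$j, 1]
    dy <- xyz[nb$i, 2] - xyz[nb$j, 2]
    dz <- xyz[nb$i, 3] - xyz[nb$j, 3]
    r2 <- pmax(dx * dx + dy * dy + dz * dz, 0.01)
    u3 <- (nb$rmin2 / r2)^3
    e <- e + sum(nb$eps * (u3 * u3 - 2 * u3)) + sum(nb$qq / r2)
  }
  s <- sys$solv
  if (!is.null(s)) {
    dx <- xyz[s$i, 1] - xyz[s$j, 1]
    dy <- xyz[s$i, 2] - xyz[s$j, 2]
    dz <- xyz[s$i, 3] - xyz[s$j, 3]
    r2 <- dx * dx + dy * dy + dz * dz
    keep <- r2 < cutoff^2
    if (any(keep)) {
      r <- sqrt(r2[keep])
      xi <- (r - s$r_i[keep]) / s$l_i[keep]
      xj <- (r - s$r_j[keep]) / s$l_j[keep]
      e <- e - sum((s$a_ij[keep] * exp(-xi * xi) +
                      s$a_ji[keep] * exp(-xj * xj)) / r2[keep])
    }
  }
  e
}

# cross-interaction system between a rigid group and a mobile group
cross_system <- function(atoms_fixed, atoms_mobile, params = ff_params()) {
  ffa <- assign_ff(atoms_fixed, params)
  ffb <- assign_ff(atoms_mobile, params)
  list(xyz_fixed = as.matrix(atoms_fixed[, c("x", "y", "z")]),
       rmin2 = outer(ffa$rmin_half, ffb$rmin_half, "+")^2,
       eps = outer(ffa$epsilon, ffb$epsilon) ^ 0.5,
       qq = params$coulomb_constant * outer(ffa$charge, ffb$charge) / 4)
}

cross_energy <- function(cx, xyz_mobile) {
  r2 <- outer(rowSums(cx$xyz_fixed^2), rowSums(xyz_mobile^2), "+") -
    2 * cx$xyz_fixed %*% t(xyz_mobile)
  r2 <- pmax(r2, 0.01)
  u3 <- (cx$rmin2 / r2)^3
  sum(cx$eps * (u3 * u3 - 2 * u3)) + sum(cx$qq / r2)
}
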