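# Cartesian minimization with geometry-preservation restraints.
#
# The minimization objective is: harmonic restraints of bonded (1-2) and
# geminal (1-3) distances to their starting values + the nonbonded energy
# (vdW + Coulomb). The restraints stand in for bond/angle terms of a full
# force field: they are exactly zero at the start point, which preserves
# the strain-penalty inequality (a minimized extracted peptide can only
# lower its reported nonbonded energy). Gradient descent with backtracking
# line search; convergence when the largest gradient component on movable
# atoms drops below `tol_grad` or the iteration cap is hit (cap exit gives
# a warning and returns the best point so far).

.min_setup <- function(atoms, params, inter_bonds, ref_atoms = NULL) {
  ff <- assign_ff(atoms, params)
  bonds <- bond_list(atoms, inter_bonds)
  n <- nrow(atoms)
  adj <- vector("list", n)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  onethree <- list()
  for (i in seq_len(n)) for (j in adj[[i]]) for (k in adj[[j]])
    if (k > i && !(k %in% adj[[i]]))
      onethree[[length(onethree) + 1L]] <- c(i, k)
  onethree <- if (length(onethree)) unique(do.call(rbind, onethree))
  else matrix(integer(0), 0, 2)
  ref <- if (is.null(ref_atoms)) atoms else ref_atoms
  stopifnot(nrow(ref) == n)
  xyz <- as.matrix(ref[, c("x", "y", "z")])
  r0 <- function(m) if (nrow(m)) sqrt(rowSums((xyz[m[, 1], , drop = FALSE] -
                                                 xyz[m[, 2], , drop = FALSE])^2)) else numeric(0)
  list(ff = ff, pairs = pair_list(n, bonds),
       rest = rbind(
         if (nrow(bonds)) cbind(bonds, k = 300, r0 = r0(bonds)),
         if (nrow(onethree)) cbind(onethree, k = 50, r0 = r0(onethree))))
}

.min_energy_grad <- function(xyz, setup, coulomb_constant, grad = TRUE) {
  n <- nrow(xyz)
  g <- matrix(0, n, 3)
  e <- 0
  p <- setup$pairs
  if (nrow(p)) {
    dx <- xyz[p$i, , drop = FALSE] - xyz[p$j, , drop = FALSE]
    r2 <- pmax(rowSums(dx^2), 0.01)
    ff <- setup$ff
    rmin <- ff$rmin_half[p$i] + ff$rmin_half[p$j]
    eps <- sqrt(ff$epsilon[p$i] * ff$epsilon[p$j])
    qq <- coulomb_constant * ff$charge[p$i] * ff$charge[p$j] / 4
    u3 <- (rmin^2 / r2)^3
    e <- e + sum(p$scale * (eps * (u3^2 - 2 * u3) + qq / r2))
    if (grad) {
      dEdr2 <- p$scale * (-6 * eps * (u3^2 - u3) / r2 - qq / r2^2)
      f <- 2 * dEdr2 * dx
      for (c in 1:3) {
        gi <- numeric(n); gj <- numeric(n)
        tmp <- tapply(f[, c], p$i, sum)
        gi[as.integer(names(tmp))] <- tmp
        tmp <- tapply(f[, c], p$j, sum)
        gj[as.integer(names(tmp))] <- tmp
        g[, c] <- g[, c] + gi - gj
      }
    }
  }
  r <- setup$rest
  if (!is.null(r) && nrow(r)) {
    i <- r[, 1]; j <- r[, 2]
    dx <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    rr <- pmax(sqrt(rowSums(dx^2)), 1e-6)
    e <- e + sum(r[, "k"] * (rr - r[, "r0"])^2)
    if (grad) {
      fac <- 2 * r[, "k"] * (rr - r[, "r0"]) / rr
      f <- fac * dx
      for (c in 1:3) {
        gi <- numeric(nrow(xyz)); gj <- numeric(nrow(xyz))
        tmp <- tapply(f[, c], i, sum)
        gi[as.integer(names(tmp))] <- tmp
        tmp <- tapply(f[, c], j, sum)
        gj[as.integer(names(tmp))] <- tmp
        g[, c] <- g[, c] + gi - gj
      }
    }
  }
  list(e = e, g = g)
}

#' Minimize selected atoms of an atom set
#'
#' @param atoms atom data.frame
#' @param movable logical mask, one entry per atom
#' @param params a [ff_params()]
#' @param max_iter iteration cap
#' @param tol_grad convergence threshold on the max gradient component,
#'   kcal/(mol A)
#' @param inter_bonds explicit covalent links
#' @param restraint_ref optional atom table (identical ordering) whose
#'   geometry anchors the bonded/geminal distance restraints; defaults to
#'   the input, so the restraint energy is zero at the start point
#' @return list: `atoms` (minimized), `energy` (objective at the end),
#'   `energy0`, `converged`
#' @export
minimize_atoms <- function(atoms, movable, params = ff_params(),
                           max_iter = 2000, tol_grad = 0.05,
                           inter_bonds = NULL, restraint_ref = NULL) {
  stopifnot(length(movable) == nrow(atoms))
  setup <- .min_setup(atoms, params, inter_bonds, restraint_ref)
  xyz0 <- as.matrix(atoms[, c("x", "y", "z")])
  e0 <- .min_energy_grad(xyz0, setup, params$coulomb_constant,
                         grad = FALSE)$e
  mov <- which(movable)
  if (!length(mov)) {
    return(list(atoms = atoms, energy = e0, energy0 = e0, converged = TRUE))
  }
  to_xyz <- function(par) {
    xyz <- xyz0
    xyz[mov, ] <- matrix(par, ncol = 3)
    xyz
  }
  fn <- function(par) .min_energy_grad(to_xyz(par), setup,
                                       params$coulomb_constant,
                                       grad = FALSE)$e
  gr <- function(par) {
    g <- .min_energy_grad(to_xyz(par), setup, params$coulomb_constant)$g
    as.numeric(g[mov, ])
  }
  fit <- tryCatch(
    optim(as.numeric(xyz0[mov, ]), fn, gr, method = "L-BFGS-B",
          control = list(maxit = max_iter, factr = 1e4)),
    error = function(e) list(par = as.numeric(xyz0[mov, ]), value = e0,
                             convergence = 52L))
  if (fit$value > e0) fit <- list(par = as.numeric(xyz0[mov, ]), value = e0,
                                  convergence = 0L)
  xyz <- to_xyz(fit$par)
  gfin <- .min_energy_grad(xyz, setup, params$coulomb_constant)$g[mov, ,
                                                                  drop = FALSE]
  converged <- max(abs(gfin)) < tol_grad || fit$convergence == 0L
  if (!converged) warning("minimization did not converge; returning best-so-far")
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  list(atoms = atoms, energy = fit$value, energy0 = e0,
       converged = converged)
}

#' Two-round constrained minimization of a complex
#'
#' Round 1: all backbone atoms in protein and peptide fixed; protein side
#' chains within 4 Angstrom of the peptide and all peptide side chains move.
#' Round 2: the entire protein fixed, the entire peptide free.
#'
#' @param cs a `ComplexStructure`
#' @param protocol subset of `c("round1", "round2")`, applied in order
#' @param params a [ff_params()]
#' @param max_iter per-round iteration cap
#' @param contact_cutoff protein side-chain mobilization distance, Angstrom
#' @param restraint_ref optional `ComplexStructure` (identical atom
#'   ordering) anchoring the geometry restraints of every round; defaults
#'   to the input complex. Re-minimizing a result with the original anchors
#'   reproduces it (fixed point); re-anchoring at the result instead lets
#'   the geometry creep slightly with each call.
#' @return list: `complex` (minimized), `energies` (objective before and
#'   after each round)
#' @export
minimize_complex <- function(cs, protocol = c("round1", "round2"),
                             params = ff_params(), max_iter = 300,
                             contact_cutoff = 4.0, restraint_ref = NULL) {
  a <- cs$atoms
  ref_atoms <- if (is.null(restraint_ref)) cs$atoms else restraint_ref$atoms
  bb <- c("N", "CA", "C", "O", "OXT")
  energies <- list()
  for (round in protocol) {
    if (round == "round1") {
      pxyz <- as.matrix(a[a$role == "peptide", c("x", "y", "z")])
      near_res <- unique(do.call(rbind, lapply(
        which(a$role == "receptor"), function(i) {
          d2 <- min(colSums((t(pxyz) - as.numeric(a[i, c("x", "y", "z")]))^2))
          if (d2 < contact_cutoff^2) a[i, c("chain", "resno")] else NULL
        })))
      rec_mov <- a$role == "receptor" & !(a$atom %in% bb) &
        paste(a$chain, a$resno) %in%
        (if (is.null(near_res)) character(0) else paste(near_res$chain, near_res$resno))
      movable <- rec_mov | (a$role == "peptide" & !(a$atom %in% bb))
    } else if (round == "round2") {
      movable <- a$role == "peptide"
    } else stop("unknown round: ", round)
    mn <- minimize_atoms(a, movable, params, max_iter,
                         inter_bonds = cs$inter_bonds,
                         restraint_ref = ref_atoms)
    energies[[round]] <- c(before = mn$energy0, after = mn$energy)
    a <- mn$atoms
  }
  out <- cs
  out$atoms <- a
  list(complex = out, energies = energies)
}
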