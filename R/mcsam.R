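# Multiple-copy simulated annealing with minimization (MCSAM) in dihedral
# space.
#
# Sampling operates on per-residue (phi, psi) torsions with fixed template
# bond lengths and angles (omega held trans). Each run initializes a stack
# of random minimized conformations; every Monte-Carlo step perturbs a
# randomly chosen stack member, minimizes the result, applies a Metropolis
# test on minimized energies along a geometric annealing ladder, and
# maintains the bounded, diversity-aware stack. Published run sizes are
# 100-member initial stacks, 200-capacity stacks, 10,000 steps and 500
# runs; desk-scale work uses far smaller values through the same interface
# (see the `desk` profile in `default_config()`).

new_conformation <- function(residues, torsions, energy = NA_real_,
                             atoms = NULL, tmpl = NULL) {
  if (is.null(atoms)) {
    if (is.null(tmpl)) {
      atoms <- build_peptide(residues, phi = torsions[, 1],
                             psi = torsions[, 2])
    } else {
      atoms <- tmpl
      xyz <- build_peptide_xyz(residues, torsions[, 1], torsions[, 2])$xyz
      atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    }
  }
  structure(list(torsions = torsions, atoms = atoms, energy = energy),
            class = "DihedralConformation")
}

# internal energy of a peptide conformation: nonbonded + implicit solvation
conformation_energy <- function(atoms, params) {
  nonbonded_energy(atoms)$total + solvation_energy(atoms, params)
}

# torsion-space minimization (numerical-gradient BFGS on the energy surface)
.minimize_torsions <- function(residues, torsions, efun, maxit = 15,
                               tmpl = NULL) {
  x0 <- as.numeric(torsions)
  obj <- function(x) {
    tor <- matrix(x, ncol = 2)
    efun(tor, build_peptide_xyz(residues, tor[, 1], tor[, 2])$xyz)
  }
  fit <- tryCatch(
    optim(x0, obj, method = "BFGS", control = list(maxit = maxit)),
    error = function(e) list(par = x0, value = obj(x0)))
  if (fit$value > obj(x0) + 1e-9) fit <- list(par = x0, value = obj(x0))
  tor <- matrix(fit$par, ncol = 2)
  new_conformation(residues, tor, fit$value, tmpl = tmpl)
}

# stack maintenance: sorted by energy, capacity-capped, diversity-aware.
# A candidate within `diversity_radius` of an existing member replaces that
# member only when lower in energy; otherwise it is inserted if the stack
# has room or beats the worst member.
.stack_insert <- function(stack, cand, capacity = 200, diversity_radius = 0.5) {
  for (k in seq_along(stack)) {
    r <- tryCatch(rmsd_bb_cb(stack[[k]], cand), error = function(e) Inf)
    if (r <= diversity_radius) {
      if (cand$energy < stack[[k]]$energy) stack[[k]] <- cand
      return(stack[order(vapply(stack, `[[`, numeric(1), "energy"))])
    }
  }
  if (length(stack) < capacity) {
    stack[[length(stack) + 1L]] <- cand
  } else {
    en <- vapply(stack, `[[`, numeric(1), "energy")
    worst <- which.max(en)
    if (cand$energy < en[worst]) stack[[worst]] <- cand else return(stack)
  }
  stack[order(vapply(stack, `[[`, numeric(1), "energy"))]
}

#' Full conformational sampling of a peptide (MCSAM)
#'
#' @param sequence extended-notation string or parsed residues
#' @param runs independent runs (published scale: 500)
#' @param steps_per_run Monte-Carlo-with-minimization steps per run
#'   (published scale: 10,000)
#' @param seed integer seed; the full pipeline is deterministic per seed
#' @param init_size random minimized conformations seeding each run's stack
#'   (published scale: 100)
#' @param capacity stack capacity (published scale: 200)
#' @param diversity_radius stack diversity radius, Angstrom
#' @param t_hot,t_cold annealing ladder endpoints, K (geometric schedule)
#' @param p_rama probability of a Ramachandran-map move (the alternative is
#'   a local Gaussian perturbation of one torsion, sigma 30 degrees)
#' @param rama logical; disable to sample without bias maps
#' @param params force-field parameters
#' @param energy_fn optional override `function(torsions, xyz) -> energy`
#'   taking the torsion matrix and the built coordinate matrix (used for
#'   controlled sampling experiments); default is the internal nonbonded +
#'   solvation model on a precomputed topology
#' @param minimize_maxit iteration cap of the embedded minimization
#' @return list of class `ConformerEnsemble`: `conformations` (each with
#'   torsions, atoms, energy), `sequence`, `runs`
#' @export
run_sampling <- function(sequence, runs = 500, steps_per_run = 10000,
                         seed = 1L, init_size = 100, capacity = 200,
                         diversity_radius = 0.5, t_hot = 1000, t_cold = 300,
                         p_rama = 0.8, rama = TRUE, params = ff_params(),
                         energy_fn = NULL, minimize_maxit = 15) {
  residues <- if (is.character(sequence)) parse_peptide_sequence(sequence)
  else sequence
  n <- nrow(residues)
  tmpl <- build_peptide(residues)
  sys <- pep_system(tmpl, params)
  efun <- if (is.null(energy_fn))
    function(tor, xyz) sys_energy(sys, xyz) else energy_fn
  rmap <- if (rama && is.null(energy_fn)) precompute_rama(residues,
                                                          params = params)
  else NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  all_conf <- list()
  temps <- t_hot * (t_cold / t_hot)^(seq_len(max(1, steps_per_run)) /
                                       max(1, steps_per_run))
  for (run in seq_len(runs)) {
    stack <- list()
    for (k in seq_len(init_size)) {
      tor <- matrix(runif(2 * n, -180, 180), ncol = 2)
      cand <- .minimize_torsions(residues, tor, efun, minimize_maxit, tmpl)
      stack <- .stack_insert(stack, cand, capacity, diversity_radius)
    }
    for (step in seq_len(steps_per_run)) {
      parent <- stack[[sample.int(length(stack), 1)]]
      tor <- parent$torsions
      i <- sample.int(n, 1)
      if (!is.null(rmap) && runif(1) < p_rama) {
        tor[i, ] <- sample_rama(rmap, i)
      } else {
        j <- sample.int(2, 1)
        tor[i, j] <- ((tor[i, j] + rnorm(1, 0, 30) + 180) %% 360) - 180
      }
      cand <- .minimize_torsions(residues, tor, efun, minimize_maxit, tmpl)
      accept <- cand$energy <= parent$energy ||
        runif(1) < exp(-(cand$energy - parent$energy) / (kB * temps[step]))
      if (accept)
        stack <- .stack_insert(stack, cand, capacity, diversity_radius)
    }
    all_conf <- c(all_conf, stack)
  }
  en <- vapply(all_conf, `[[`, numeric(1), "energy")
  structure(list(conformations = all_conf[order(en)], sequence = residues,
                 runs = runs), class = "ConformerEnsemble")
}

#' @export
print.ConformerEnsemble <- function(x, ...) {
  en <- vapply(x$conformations, `[[`, numeric(1), "energy")
  cat(sprintf(
    "ConformerEnsemble: %d conformations from %d run(s); energy range [%.2f, %.2f] kcal/mol\n",
    length(en), x$runs, min(en), max(en)))
  invisible(x)
}

#' Energy-window filter
#'
#' Keeps conformations within `window` kcal/mol of the ensemble's lowest
#' energy (published analysis window: 15 kcal/mol).
#'
#' @param ensemble a `ConformerEnsemble`
#' @param window energy window, kcal/mol
#' @return filtered `ConformerEnsemble`
#' @export
filter_window <- function(ensemble, window = 15) {
  en <- vapply(ensemble$conformations, `[[`, numeric(1), "energy")
  stopifnot(length(en) >= 1)
  keep <- en <= min(en) + window
  out <- ensemble
  out$conformations <- ensemble$conformations[keep]
  out
}
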