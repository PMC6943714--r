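# Boltzmann-weighted binding-affinity estimation around a bound backbone.
#
# The peptide is locally sampled (torsions + rigid-body placement) in the
# field of a rigid receptor, under a flat-bottom harmonic constraint that
# lets each non-terminal backbone heavy atom move 1.0 A from its reference
# position without penalty. Each run keeps its minimum total-energy pose;
# the final affinity is the Boltzmann-weighted (by total energy) average of
# the protein-peptide interaction energy over those per-run minima. Strain
# (intra-peptide) energy deliberately does not enter the affinity itself -
# only the weights.

#' Flat-bottom backbone constraint settings
#'
#' @param tolerance penalty-free displacement, Angstrom
#' @param force_constant harmonic constant beyond the tolerance,
#'   kcal/(mol A^2); the published description leaves it unstated, 10 is
#'   the configurable default
#' @param exclude_terminal number of residues at each end left fully
#'   unconstrained (1 = the first and the last residue)
#' @return list of class `BackboneConstraint`
#' @export
backbone_constraint <- function(tolerance = 1.0, force_constant = 10,
                                exclude_terminal = 1L) {
  stopifnot(tolerance > 0, force_constant >= 0)
  structure(list(tolerance = tolerance, force_constant = force_constant,
                 exclude_terminal = as.integer(exclude_terminal)),
            class = "BackboneConstraint")
}

# constrained atom selector: backbone heavy atoms of non-terminal residues
.constrained_idx <- function(atoms, constraint) {
  rs <- sort(unique(atoms$resno))
  nt <- constraint$exclude_terminal
  inner <- rs[rs > rs[nt] & rs < rs[length(rs) + 1 - nt]]
  which(atoms$resno %in% inner & atoms$atom %in% c("N", "CA", "C", "O"))
}

#' Flat-bottom constraint energy of a pose
#'
#' Sum over constrained backbone heavy atoms of
#' `k * max(0, d_i - tolerance)^2`, where `d_i` is the displacement from
#' the reference backbone. Terminal residues contribute nothing.
#'
#' @param pose,reference peptide atom data.frames with matching
#'   (resno, atom) identities
#' @param constraint a [backbone_constraint()]
#' @return constraint energy, kcal/mol
#' @export
constraint_energy <- function(pose, reference, constraint = backbone_constraint()) {
  idx <- .constrained_idx(reference, constraint)
  if (!length(idx)) return(0)
  key <- paste(pose$resno, pose$atom)
  m <- match(paste(reference$resno[idx], reference$atom[idx]), key)
  if (anyNA(m)) stop("missing atom correspondence for constraint")
  d <- sqrt(rowSums((as.matrix(pose[m, c("x", "y", "z")]) -
                       as.matrix(reference[idx, c("x", "y", "z")]))^2))
  sum(constraint$force_constant * pmax(0, d - constraint$tolerance)^2)
}

# rotation from small-angle vector (Rodrigues)
.rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3,
               byrow = TRUE)
  diag(3) + sin(th) * kx + (1 - cos(th)) * kx %*% kx
}

# pose builder: torsions -> template coords -> reference alignment ->
# residual rigid-body transform
.make_poser <- function(cs) {
  pep <- peptide_atoms(cs)
  residues <- data.frame(code = pep$resid[!duplicated(pep$resno)],
                         is_d = pep$is_d[!duplicated(pep$resno)],
                         stringsAsFactors = FALSE)
  tor0 <- peptide_torsions(pep)
  tor0[is.na(tor0[, 1]), 1] <- -57
  tor0[is.na(tor0[, 2]), 2] <- -47
  b0 <- build_peptide(residues, phi = tor0[, 1], psi = tor0[, 2])
  sel <- c("N", "CA", "C")
  kb <- paste(b0$resno, b0$atom); kp <- paste(pep$resno, pep$atom)
  common <- intersect(kb[b0$atom %in% sel], kp[pep$atom %in% sel])
  xb <- as.matrix(b0[match(common, kb), c("x", "y", "z")])
  xp <- as.matrix(pep[match(common, kp), c("x", "y", "z")])
  cb <- colMeans(xb); cp <- colMeans(xp)
  s <- svd(crossprod(sweep(xb, 2, cb), sweep(xp, 2, cp)))
  d <- sign(det(s$v %*% t(s$u)))
  rot0 <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  build_xyz <- function(tor, rig) {
    xyz <- build_peptide_xyz(residues, tor[, 1], tor[, 2])$xyz
    xyz <- sweep(xyz, 2, cb)
    xyz <- xyz %*% t(rot0) %*% t(.rotvec(rig[1:3]))
    sweep(xyz, 2, cp + rig[4:6], "+")
  }
  list(residues = residues, tor0 = tor0, rot0 = rot0, cb = cb, cp = cp,
       build_xyz = build_xyz,
       build = function(tor, rig) {
         b <- build_peptide(residues, phi = tor[, 1], psi = tor[, 2])
         xyz <- build_xyz(tor, rig)
         b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
         b
       })
}

#' Constrained local binding sampling around a bound pose
#'
#' @param cs a `ComplexStructure` with the peptide posed in the binding
#'   site; the receptor is held rigid throughout
#' @param runs independent runs (published scale: 100)
#' @param steps_per_run Monte-Carlo-with-minimization steps per run
#'   (published scale: 2000)
#' @param constraint a [backbone_constraint()]
#' @param seed integer seed (deterministic per seed)
#' @param params force-field parameters
#' @param t_hot,t_cold annealing endpoints, K
#' @param minimize_maxit embedded minimization iteration cap
#' @return list of `BindingRun`s, each with `min_pose` (peptide atoms),
#'   `e_total` (constraint + internal + interaction) and `e_inter`
#'   (protein-peptide interaction only), kcal/mol
#' @export
run_binding_sampling <- function(cs, runs = 100, steps_per_run = 2000,
                                 constraint = backbone_constraint(),
                                 seed = 1L, params = ff_params(),
                                 t_hot = 600, t_cold = 300,
                                 minimize_maxit = 10) {
  poser <- .make_poser(cs)
  pep_ref <- peptide_atoms(cs)
  rec <- receptor_atoms(cs)
  n <- nrow(poser$residues)
  tmpl <- poser$build(poser$tor0, rep(0, 6))
  sys <- pep_system(tmpl, params)
  cx <- cross_system(rec, tmpl, params)
  cidx <- .constrained_idx(pep_ref, constraint)
  ckey <- match(paste(pep_ref$resno[cidx], pep_ref$atom[cidx]),
                paste(tmpl$resno, tmpl$atom))
  cref <- as.matrix(pep_ref[cidx, c("x", "y", "z")])
  energy_of <- function(tor, rig) {
    xyz <- poser$build_xyz(tor, rig)
    e_intra <- sys_energy(sys, xyz)
    e_inter <- cross_energy(cx, xyz)
    e_con <- 0
    if (length(ckey)) {
      d <- sqrt(rowSums((xyz[ckey, , drop = FALSE] - cref)^2))
      e_con <- sum(constraint$force_constant *
                     pmax(0, d - constraint$tolerance)^2)
    }
    c(total = e_intra + e_inter + e_con, inter = e_inter)
  }
  minimize_state <- function(tor, rig) {
    x0 <- c(as.numeric(tor), rig)
    obj <- function(x) energy_of(matrix(x[seq_len(2 * n)], ncol = 2),
                                 x[2 * n + 1:6])[["total"]]
    fit <- tryCatch(optim(x0, obj, method = "BFGS",
                          control = list(maxit = minimize_maxit)),
                    error = function(e) list(par = x0, value = obj(x0)))
    if (fit$value > obj(x0) + 1e-9) fit <- list(par = x0, value = obj(x0))
    list(tor = matrix(fit$par[seq_len(2 * n)], ncol = 2),
         rig = fit$par[2 * n + 1:6], e = fit$value)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  temps <- t_hot * (t_cold / t_hot)^(seq_len(max(1, steps_per_run)) /
                                       max(1, steps_per_run))
  out <- vector("list", runs)
  for (run in seq_len(runs)) {
    st <- minimize_state(poser$tor0, rep(0, 6))
    best <- st
    for (step in seq_len(steps_per_run)) {
      tor <- st$tor; rig <- st$rig
      if (runif(1) < 0.7) {
        i <- sample.int(n, 1); j <- sample.int(2, 1)
        tor[i, j] <- ((tor[i, j] + rnorm(1, 0, 30) + 180) %% 360) - 180
      } else {
        rig <- rig + c(rnorm(3, 0, 5 * pi / 180), rnorm(3, 0, 0.3))
      }
      cand <- minimize_state(tor, rig)
      if (cand$e <= st$e ||
          runif(1) < exp(-(cand$e - st$e) / (kB * temps[step]))) st <- cand
      if (st$e < best$e) best <- st
    }
    eb <- energy_of(best$tor, best$rig)
    out[[run]] <- structure(
      list(min_pose = poser$build(best$tor, best$rig),
           e_total = eb[["total"]], e_inter = eb[["inter"]]),
      class = "BindingRun")
  }
  out
}

#' Boltzmann-weighted affinity estimate over per-run minimum poses
#'
#' Weights are proportional to `exp(-e_total / kT)` (total energies shifted
#' by their minimum for numerical stability) and the affinity is the
#' weighted mean of the protein-peptide interaction energies. As T -> 0 the
#' estimate approaches the interaction energy of the lowest-total-energy
#' run; as T -> Inf it approaches the plain mean.
#'
#' @param runs list of `BindingRun`s
#' @param temperature K
#' @return list of class `BoltzmannEstimate`: `weights`, `affinity`
#'   (kcal/mol), `e_total`, `e_inter`, `temperature`
#' @export
boltzmann_estimate <- function(runs, temperature = 300) {
  if (!length(runs)) stop("empty run list")
  et <- vapply(runs, `[[`, numeric(1), "e_total")
  ei <- vapply(runs, `[[`, numeric(1), "e_inter")
  if (temperature <= 0) {
    w <- as.numeric(seq_along(et) == which.min(et))
  } else {
    w <- exp(-(et - min(et)) / (kB * temperature))
    w <- w / sum(w)
  }
  structure(list(runs = runs, temperature = temperature, weights = w,
                 affinity = sum(w * ei), e_total = et, e_inter = ei),
            class = "BoltzmannEstimate")
}

#' @export
print.BoltzmannEstimate <- function(x, ...) {
  cat(sprintf(
    "BoltzmannEstimate: %d runs at %g K; affinity %.3f kcal/mol (e_inter range [%.2f, %.2f])\n",
    length(x$weights), x$temperature, x$affinity, min(x$e_inter),
    max(x$e_inter)))
  invisible(x)
}

#' Receptor-pair selectivity of one peptide
#'
#' Difference of Boltzmann-weighted affinities of the same peptide against
#' two receptors, computed with shared settings and seeds so the comparison
#' is paired.
#'
#' @param complex_a,complex_b `ComplexStructure`s of the peptide bound to
#'   receptor A and receptor B
#' @param runs,steps_per_run,constraint,seed,params,temperature shared
#'   sampling settings
#' @return `affinity(A) - affinity(B)`, kcal/mol (negative favors A when
#'   affinities are interaction energies)
#' @export
selectivity <- function(complex_a, complex_b, runs = 100,
                        steps_per_run = 2000,
                        constraint = backbone_constraint(), seed = 1L,
                        params = ff_params(), temperature = 300) {
  ea <- boltzmann_estimate(
    run_binding_sampling(complex_a, runs, steps_per_run, constraint, seed,
                         params), temperature)
  eb <- boltzmann_estimate(
    run_binding_sampling(complex_b, runs, steps_per_run, constraint, seed,
                         params), temperature)
  ea$affinity - eb$affinity
}

#' Mutate one peptide residue in place
#'
#' Replaces the residue's side chain with the new residue's C-beta stub
#' (side chains beyond C-beta are left for minimization/sampling to refine;
#' a D target mirrors the C-beta chirality). Backbone atoms are untouched.
#'
#' @param cs a `ComplexStructure`
#' @param resno peptide residue number
#' @param new_code three-letter code of the replacement
#' @param to_d logical; build the D enantiomer
#' @return modified `ComplexStructure`
#' @export
mutate_peptide <- function(cs, resno, new_code, to_d = FALSE) {
  new_code <- toupper(new_code)
  if (!new_code %in% known_residues()) stop("unknown residue: ", new_code)
  a <- cs$atoms
  sel <- a$role == "peptide" & a$resno == resno
  if (!any(sel)) stop("peptide residue not found: ", resno)
  bb <- c("N", "CA", "C", "O", "OXT")
  keep <- !sel | a$atom %in% bb
  a <- a[keep, , drop = FALSE]
  sel <- a$role == "peptide" & a$resno == resno
  a$resid[sel] <- new_code
  a$is_d[sel] <- to_d
  if (new_code != "GLY") {
    g <- function(nm) as.numeric(a[sel & a$atom == nm, c("x", "y", "z")])
    cb <- place_atom(g("C"), g("N"), g("CA"), 1.530, 110.5,
                     if (to_d) 122.6 else -122.6)
    row <- a[sel & a$atom == "CA", , drop = FALSE]
    row$atom <- "CB"; row$element <- "C"
    row$x <- cb[1]; row$y <- cb[2]; row$z <- cb[3]
    a <- rbind(a, row)
  }
  rec <- a[a$role == "receptor", ]; pep <- a[a$role == "peptide", ]
  pep <- pep[order(pep$resno), ]
  new_complex(rec, pep, cs$inter_bonds, cs$uncapped)
}
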