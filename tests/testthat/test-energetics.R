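# Force-field terms, solvation, binding-energy flavors, minimization
# protocol.

test_that("pair terms: LJ minimum, 4d-dielectric Coulomb, decay", {
  p <- ff_params()
  a <- atom_row("C1", "C", 0, 0, 0, resid = "XXX")
  b <- atom_row("C2", "C", 2 * 1.908, 0, 0, resid = "XXX", chain = "B")
  nb <- nonbonded_energy(a, b, p)
  expect_equal(nb$vdw, -0.1094, tolerance = 1e-9)
  expect_equal(nb$coulomb, 0)

  # +0.6 e (Lys NZ) and -0.45 e (Asp OD1) at 3.0 A under eps = 4d
  la <- atom_row("NZ", "N", 0, 0, 0, "LYS")
  lb <- atom_row("OD1", "O", 3, 0, 0, "ASP", chain = "B")
  nb2 <- nonbonded_energy(la, lb, p)
  expect_equal(nb2$coulomb, 332.0636 * 0.6 * (-0.45) / (4 * 9),
               tolerance = 1e-9)

  far <- atom_row("C2", "C", 100, 0, 0, resid = "XXX", chain = "B")
  expect_lt(abs(nonbonded_energy(a, far, p)$total), 0.01)
})

test_that("energy breakdowns are exact component sums and symmetric", {
  eb <- energy_breakdown(1.25, -3.5, 0.75, 2)
  expect_identical(eb$total, 1.25 - 3.5 + 0.75 + 2)
  a <- random_cluster(5, seed = 11); a$chain <- "A"
  b <- random_cluster(4, seed = 12); b$chain <- "B"
  b$x <- b$x + 8
  eab <- nonbonded_energy(a, b)
  eba <- nonbonded_energy(b, a)
  expect_equal(eab$total, eba$total, tolerance = 1e-12)
  expect_equal(eab$total, eab$vdw + eab$coulomb)
})

test_that("energy terms are invariant under rigid motion", {
  set.seed(5)
  atoms <- build_ideal_helix("ASA")
  p <- ff_params()
  e0 <- nonbonded_energy(atoms)$total
  s0 <- solvation_energy(atoms, p)
  for (rep in 1:3) {
    rot <- pepforge:::random_rotation()
    sh <- rnorm(3, 0, 10)
    a2 <- atoms
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
    a2$x <- xyz[, 1] + sh[1]; a2$y <- xyz[, 2] + sh[2]; a2$z <- xyz[, 3] + sh[3]
    expect_equal(nonbonded_energy(a2)$total, e0, tolerance = 1e-8)
    expect_equal(solvation_energy(a2, p), s0, tolerance = 1e-8)
  }
})

test_that("solvation: exposed atom gives its reference energy, burial subtracts the exclusion sum", {
  p <- ff_params()
  one <- atom_row("CB", "C", 0, 0, 0) # Ala CB: methyl (CH3E) reference
  expect_equal(solvation_energy(one, p), 1.089, tolerance = 1e-9)

  # caged atom: direct independent summation of the Gaussian exclusion term
  cage <- pepforge:::.icosahedron() * 4.0
  atoms <- rbind(one, do.call(rbind, lapply(seq_len(nrow(cage)), function(i)
    atom_row("CB", "C", cage[i, 1], cage[i, 2], cage[i, 3], resno = i + 1))))
  mine <- solvation_energy(atoms, p)
  # oracle: explicit double loop over the model definition
  lam <- 3.5; vol <- 30.0; dgref <- 1.089; rad <- 1.70
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  excl <- 0
  for (i in seq_len(nrow(xyz))) for (j in seq_len(nrow(xyz))) {
    if (i == j) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < 9) excl <- excl + 2 * dgref / (4 * pi * sqrt(pi) * lam) *
        exp(-((r - rad) / lam)^2) / r^2 * vol
  }
  expect_equal(mine, nrow(xyz) * dgref - excl, tolerance = 1e-9)
})

test_that("binding-energy flavors satisfy their defining relations", {
  # far-separated components bind with ~zero energy
  rec <- atom_row("CB", "C", 0, 0, 0)
  pep <- atom_row("CB", "C", 100, 0, 0, chain = "B")
  expect_lt(abs(binding_energy(new_complex(rec, pep), "simple")), 0.01)

  # strain penalty is non-negative for any complex
  for (cs in list(helix_on_sheet("AAA"), salt_bridge_complex(3.2))) {
    be_simple <- binding_energy(cs, "simple")
    be_strain <- suppressWarnings(binding_energy(cs, "strain"))
    expect_gte(be_strain, be_simple - 1e-6)
  }

  # neutralizing charges weakens a pure salt-bridge interface
  sb <- salt_bridge_complex(3.2)
  expect_lt(abs(binding_energy(sb, "neutralized")),
            abs(binding_energy(sb, "simple")))
})

test_that("two-round minimization: monotone energy, frozen atoms stay put", {
  cs <- helix_on_sheet("ASA", zgap = -5)
  mn <- suppressWarnings(minimize_complex(cs, max_iter = 60))
  expect_lte(mn$energies$round1[["after"]], mn$energies$round1[["before"]])
  expect_lte(mn$energies$round2[["after"]], mn$energies$round2[["before"]])
  # the receptor never moves in either round here (sheet is > 4 A away from
  # any peptide atom except through space; its side chains are single CB
  # atoms, so check identity where the mask said fixed)
  a0 <- cs$atoms; a1 <- mn$complex$atoms
  rec <- a0$role == "receptor"
  bb0 <- as.matrix(a0[rec, c("x", "y", "z")])
  bb1 <- as.matrix(a1[rec, c("x", "y", "z")])
  # round 2 freezes all receptor atoms; round 1 may move near side chains
  # but this receptor has no residue within 4 A (zgap -5 from CB radii)
  d <- sqrt(rowSums((bb0 - bb1)^2))
  near <- apply(bb0, 1, function(v)
    min(sqrt(rowSums((as.matrix(a0[a0$role == "peptide",
                                   c("x", "y", "z")]) -
                        matrix(v, sum(a0$role == "peptide"), 3,
                               byrow = TRUE))^2))) < 4)
  expect_true(all(d[!near] < 1e-9))
})

test_that("minimization at a local minimum leaves coordinates unchanged", {
  cs <- helix_on_sheet("AA", zgap = -8)
  m1 <- suppressWarnings(minimize_complex(cs, "round2", max_iter = 2000))
  # same objective (restraints anchored to the original geometry): the
  # first result is a fixed point of the second call
  m2 <- suppressWarnings(minimize_complex(m1$complex, "round2",
                                          max_iter = 2000,
                                          restraint_ref = cs))
  expect_lt(m2$energies$round2[["before"]] - m2$energies$round2[["after"]],
            1e-4)
  d <- max(abs(as.matrix(m1$complex$atoms[, c("x", "y", "z")]) -
                 as.matrix(m2$complex$atoms[, c("x", "y", "z")])))
  expect_lt(d, 0.05)
})

test_that("receptor side chains beyond 4 A are frozen in round 1", {
  pep <- build_ideal_helix("AA")
  rec <- rbind(atom_row("CA", "C", 0, 0, -11.0),
               atom_row("CB", "C", 0, 1.53, -11.0)) # CB > 4 A from peptide
  rec$resno <- 1
  cs <- new_complex(rec, pep)
  dmin <- min(as.matrix(stats::dist(rbind(
    as.matrix(rec[, c("x", "y", "z")]),
    as.matrix(pep[, c("x", "y", "z")]))))[1:2, -(1:2)])
  expect_gt(dmin, 4) # fixture premise: receptor beyond the mobilization cutoff
  mn <- suppressWarnings(minimize_complex(cs, "round1", max_iter = 40))
  expect_equal(unname(as.matrix(
    mn$complex$atoms[mn$complex$atoms$role == "receptor",
                     c("x", "y", "z")])),
    unname(as.matrix(rec[, c("x", "y", "z")])), tolerance = 1e-12)
})

test_that("unparameterized atoms are rejected", {
  bad <- atom_row("XX", "ZZ", 0, 0, 0, resid = "XXX")
  expect_error(nonbonded_energy(bad), "unparameterized")
})
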