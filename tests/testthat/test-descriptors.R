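# SASA engine, burial, hydrogen bonds, salt bridges, descriptor assembly.

test_that("SASA: isolated-sphere closed form and far-apart additivity", {
  a <- atom_row("C1", "C", 0, 0, 0, resid = "XXX")
  s <- compute_sasa(a)
  expect_equal(s$total, 4 * pi * 3.10^2, tolerance = 1e-9)
  expect_equal(s$total, sum(s$per_atom_area))

  two <- rbind(atom_row("C1", "C", 0, 0, 0, resid = "XXX"),
               atom_row("C2", "C", 100, 0, 0, resid = "XXX", resno = 2))
  s2 <- compute_sasa(two)
  expect_equal(s2$per_atom_area, rep(4 * pi * 3.10^2, 2), tolerance = 1e-9)

  expect_error(compute_sasa(atom_row("X", "ZZ", 0, 0, 0)), "no radius")
})

test_that("SASA matches an independent dense-point oracle within 1%", {
  for (seed in c(2, 17, 31)) {
    n <- sample(5:20, 1)
    cl <- random_cluster(n, spread = 3.5, seed = seed)
    mine <- compute_sasa(cl)$total
    orac <- oracle_sasa(cl, n_points = 40000, seed = seed + 1)
    expect_lt(abs(mine - orac) / orac, 0.01)
  }
})

test_that("burial: zero when separated, full for an occluded atom, symmetric in role", {
  # separated components bury nothing
  rec <- atom_row("CB", "C", 0, 0, 0)
  pep <- atom_row("CB", "C", 100, 0, 0, chain = "B")
  cs <- new_complex(rec, pep)
  b <- compute_burial(cs)
  expect_equal(b$buried_SA, 0)

  # icosahedral cage fully occludes the central atom
  cage <- make_toy_complex(toy_spec(n_buried_hydrophobic = 1,
                                    geometry_seed = 8))
  bb <- compute_burial(cage)
  pep_cb <- which(cage$atoms$role == "peptide" & cage$atoms$atom == "CB")
  iso <- compute_sasa(peptide_atoms(cage))$per_atom_area
  iso_cb <- iso[which(peptide_atoms(cage)$atom == "CB")]
  expect_lt(abs(bb$dsasa[pep_cb] - iso_cb) / iso_cb, 0.05)

  # mirror-symmetric interface: both sides bury the same area
  recs <- rbind(atom_row("CB", "C", -1.6, 0, 0),
                atom_row("CB", "C", -1.6, 3, 0, resno = 2))
  peps <- rbind(atom_row("CB", "C", 1.6, 0, 0, chain = "B"),
                atom_row("CB", "C", 1.6, 3, 0, chain = "B", resno = 2))
  sym <- new_complex(recs, peps)
  bs <- compute_burial(sym)
  rec_side <- sum(bs$dsasa[sym$atoms$role == "receptor"])
  pep_side <- sum(bs$dsasa[sym$atoms$role == "peptide"])
  expect_lt(abs(rec_side - pep_side) / max(rec_side, 1e-12), 0.01)
})

test_that("buried area is non-increasing as the peptide moves away", {
  prev <- Inf
  for (gap in c(3.5, 5, 7, 12, 30)) {
    rec <- rbind(atom_row("CB", "C", 0, 0, 0),
                 atom_row("CB", "C", 0, 2.5, 0, resno = 2))
    pep <- rbind(atom_row("CB", "C", gap, 0, 0, chain = "B"),
                 atom_row("CB", "C", gap, 2.5, 0, chain = "B", resno = 2))
    b <- compute_burial(new_complex(rec, pep))
    expect_lte(b$buried_SA, prev + 1e-9)
    prev <- b$buried_SA
  }
  expect_equal(prev, 0)
})

test_that("hydrogen-bond counting follows the geometric criteria", {
  mk <- function(no_dist) {
    rec <- rbind(atom_row("C", "C", -1.23, 0, 0),
                 atom_row("O", "O", 0, 0, 0))
    pep <- rbind(atom_row("N", "N", no_dist, 0, 0, "GLY", chain = "B"),
                 atom_row("CA", "C", no_dist + 1.458, 0, 0, "GLY", chain = "B"))
    new_complex(rec, pep)
  }
  expect_identical(count_hbonds(mk(2.9)), 1L)
  expect_identical(count_hbonds(mk(4.5)), 0L)
  # k independent constructed bonds -> k
  for (k in c(2L, 5L)) {
    cs <- make_toy_complex(toy_spec(n_hbonds = k, geometry_seed = k))
    expect_identical(count_hbonds(cs), k)
  }
  # bad approach angle (acceptor behind the donor's H direction) -> 0
  rec <- rbind(atom_row("C", "C", -1.23, 0, 0),
               atom_row("O", "O", 0, 0, 0))
  pep <- rbind(atom_row("N", "N", 2.9, 0, 0, "GLY", chain = "B"),
               atom_row("CA", "C", 2.9, -1.458, 0, "GLY", chain = "B"))
  cs <- new_complex(rec, pep) # inferred H points at 90 degrees to O
  expect_identical(count_hbonds(cs), 0L)
})

test_that("salt bridges: favorable, absent, and net conventions", {
  expect_identical(count_salt_bridges(salt_bridge_complex(3.2)), 1L)
  expect_identical(count_salt_bridges(salt_bridge_complex(8.0)), 0L)
  cs <- make_toy_complex(toy_spec(n_salt_bridges = 1,
                                  n_like_charge_contacts = 1,
                                  geometry_seed = 6))
  expect_identical(count_salt_bridges(cs), 0L)
})

test_that("interface counts are invariant under rigid motion", {
  cs <- make_toy_complex(toy_spec(n_hbonds = 2, n_salt_bridges = 1,
                                  n_like_charge_contacts = 1,
                                  geometry_seed = 12))
  h0 <- count_hbonds(cs); s0 <- count_salt_bridges(cs)
  set.seed(42)
  for (rep in 1:3) {
    rot <- pepforge:::random_rotation()
    shift <- rnorm(3, 0, 20)
    cs2 <- cs
    xyz <- as.matrix(cs$atoms[, c("x", "y", "z")]) %*% t(rot)
    cs2$atoms$x <- xyz[, 1] + shift[1]
    cs2$atoms$y <- xyz[, 2] + shift[2]
    cs2$atoms$z <- xyz[, 3] + shift[3]
    expect_identical(count_hbonds(cs2), h0)
    expect_identical(count_salt_bridges(cs2), s0)
  }
})

test_that("descriptor assembly: zeros when separated, exact counts, linear conversion", {
  rec <- atom_row("CB", "C", 0, 0, 0)
  pep <- atom_row("CB", "C", 100, 0, 0, chain = "B")
  d0 <- compute_descriptors(new_complex(rec, pep))
  expect_equal(c(d0$dXH, d0$dXC, d0$XHB, d0$XSB, d0$buried_SA),
               c(0, 0, 0, 0, 0))

  cs <- make_toy_complex(toy_spec(n_hbonds = 2, n_salt_bridges = 1,
                                  geometry_seed = 20))
  d <- compute_descriptors(cs)
  expect_identical(d$XHB, 2L)
  expect_identical(d$XSB, 1L)

  d1 <- compute_descriptors(cs, conversion = 0.025)
  d2 <- compute_descriptors(cs, conversion = 0.050)
  expect_equal(d2$dXH, 2 * d1$dXH)
  expect_equal(d2$dXC, 2 * d1$dXC)
  expect_identical(d2$XHB, d1$XHB)
  expect_identical(d2$XSB, d1$XSB)
})

test_that("packing surrogate metrics are finite and feed the combiner", {
  cs <- helix_on_sheet()
  pm <- packing_metrics(cs)
  v <- c(pm$dihedral_normality, pm$packing1d_normality,
         pm$packing3d_normality)
  expect_true(all(is.finite(v)))
  expect_true(is.finite(packing_score(pm)))
})
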