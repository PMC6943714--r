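# Ramachandran maps, RMSD, clustering, MCSAM sampler.

test_that("Ramachandran maps are normalized with the required symmetries", {
  rg <- precompute_rama("GGG")
  m <- rg$maps[[2]]
  expect_equal(sum(m), 1, tolerance = 1e-9)
  # achiral residue: map symmetric under (phi, psi) -> (-phi, -psi)
  expect_lt(max(abs(m - m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))])),
            1e-12)
  # D map is the point reflection of the L map
  ra <- precompute_rama("AAA"); rd <- precompute_rama("aaa")
  expect_lt(max(abs(rd$maps[[2]] -
                      ra$maps[[2]][rev(seq_len(36)), rev(seq_len(36))])),
            1e-12)
  for (mm in ra$maps) expect_equal(sum(mm), 1, tolerance = 1e-9)
  expect_error(precompute_rama("A[Nope]A"), "unknown residue")
})

test_that("backbone+CB RMSD: identity, rigid motion, independent oracle", {
  a <- build_ideal_helix("AFA")
  expect_equal(rmsd_bb_cb(a, a), 0)
  rot <- pepforge:::random_rotation()
  b <- a
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  b$x <- xyz[, 1] + 3; b$y <- xyz[, 2] - 7; b$z <- xyz[, 3] + 1
  expect_lt(rmsd_bb_cb(a, b), 1e-6)

  # hand-built pair of 3-residue conformations vs an independent Kabsch
  c1 <- build_peptide("AAA", phi = c(-57, -70, -130), psi = c(-47, -20, 140))
  c2 <- build_peptide("AAA", phi = c(-60, -120, -65), psi = c(-40, 120, -35))
  sel <- c("N", "CA", "C", "O", "CB")
  k1 <- paste(c1$resno, c1$atom); k2 <- paste(c2$resno, c2$atom)
  common <- intersect(k1[c1$atom %in% sel], k2[c2$atom %in% sel])
  x1 <- as.matrix(c1[match(common, k1), c("x", "y", "z")])
  x2 <- as.matrix(c2[match(common, k2), c("x", "y", "z")])
  expect_equal(rmsd_bb_cb(c1, c2), oracle_kabsch_rmsd(x1, x2),
               tolerance = 1e-9)
  # and against the field-standard implementation with superposition
  xf <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(x1)),
                                        as.numeric(t(x2))))
  expect_equal(rmsd_bb_cb(c1, c2),
               bio3d::rmsd(as.numeric(t(x1)), xf), tolerance = 1e-3)

  expect_error(rmsd_bb_cb(build_ideal_helix("AA"), build_ideal_helix("AAA")),
               "topology mismatch")
})

test_that("energy-window filter keeps exactly the low-energy slice", {
  mk_ens <- function(energies) {
    confs <- lapply(energies, function(e) {
      cf <- pepforge:::new_conformation(parse_peptide_sequence("AA"),
                                        matrix(c(-57, -57, -47, -47), 2))
      cf$energy <- e
      cf
    })
    structure(list(conformations = confs, runs = 1),
              class = "ConformerEnsemble")
  }
  ens <- mk_ens(c(0, 10, 20))
  expect_equal(length(filter_window(ens, 15)$conformations), 2)
  expect_equal(length(filter_window(ens, Inf)$conformations), 3)
  # lowest member always retained
  expect_equal(min(vapply(filter_window(ens, 0.001)$conformations,
                          `[[`, numeric(1), "energy")), 0)
})

test_that("leader clustering: degenerate cases and radius monotonicity", {
  base <- pepforge:::new_conformation(parse_peptide_sequence("AAA"),
                                      matrix(c(-57, -57, -57, -47, -47, -47), 3))
  base$energy <- 1
  same <- structure(list(conformations = rep(list(base), 4), runs = 1),
                    class = "ConformerEnsemble")
  cl <- cluster_ensemble(same, 1.0)
  expect_equal(length(cl$representatives), 1)
  expect_equal(length(cl$members[[1]]), 4)

  spread <- lapply(list(c(-57, -47), c(60, 60), c(-150, 150)), function(t) {
    cf <- pepforge:::new_conformation(parse_peptide_sequence("AAA"),
                                      matrix(rep(t, each = 3), 3))
    cf$energy <- sum(t)
    cf
  })
  ens <- structure(list(conformations = spread, runs = 1),
                   class = "ConformerEnsemble")
  expect_equal(length(cluster_ensemble(ens, 0.1)$representatives), 3)

  ns <- vapply(c(0.5, 1.0, 2.0), function(r)
    length(cluster_ensemble(ens, r)$representatives), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("best-in-top-k cluster RMSD is exact and monotone in k", {
  ens <- run_sampling("AA", runs = 1, steps_per_run = 8, init_size = 6,
                      seed = 2, rama = FALSE, minimize_maxit = 5)
  cl <- cluster_ensemble(ens, 0.5)
  ref <- ens$conformations[[1]]$atoms
  expect_equal(min_rmsd_vs_reference(cl, ens, ref, 25), 0, tolerance = 1e-9)
  other <- build_peptide("AA", phi = 60, psi = 60)
  vals <- vapply(c(1, 2, 500), function(k)
    min_rmsd_vs_reference(cl, ens, other, k), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  # equals an exhaustive scan
  k <- min(2, length(cl$representatives))
  brute <- min(vapply(cl$representatives[seq_len(k)], function(i)
    rmsd_bb_cb(ens$conformations[[i]]$atoms, other), numeric(1)))
  expect_equal(min_rmsd_vs_reference(cl, ens, other, k), brute)
})

test_that("sampler is deterministic per seed and respects the stack cap", {
  e1 <- run_sampling("AAA", runs = 2, steps_per_run = 6, init_size = 4,
                     seed = 5, rama = FALSE, minimize_maxit = 5)
  e2 <- run_sampling("AAA", runs = 2, steps_per_run = 6, init_size = 4,
                     seed = 5, rama = FALSE, minimize_maxit = 5)
  expect_equal(vapply(e1$conformations, `[[`, numeric(1), "energy"),
               vapply(e2$conformations, `[[`, numeric(1), "energy"))
  e3 <- run_sampling("AAA", runs = 2, steps_per_run = 6, init_size = 4,
                     seed = 6, rama = FALSE, minimize_maxit = 5)
  expect_false(identical(vapply(e1$conformations, `[[`, numeric(1), "energy"),
                         vapply(e3$conformations, `[[`, numeric(1), "energy")))

  # stack capacity binds: with capacity 3 no run returns more than 3
  cap <- run_sampling("AA", runs = 2, steps_per_run = 10, init_size = 8,
                      capacity = 3, seed = 1, rama = FALSE,
                      minimize_maxit = 4)
  expect_lte(length(cap$conformations), 2 * 3)
})

test_that("stack insertion within the diversity radius never grows the stack", {
  res <- parse_peptide_sequence("AA")
  mk <- function(phi, e) {
    cf <- pepforge:::new_conformation(res, matrix(c(phi, phi, -47, -47), 2))
    cf$energy <- e
    cf
  }
  st <- list(mk(-57, 5), mk(100, 7))
  near <- mk(-57.01, 3) # within 0.5 A of member 1, lower energy
  st2 <- pepforge:::.stack_insert(st, near, capacity = 200,
                                  diversity_radius = 0.5)
  expect_equal(length(st2), 2)
  expect_equal(min(vapply(st2, `[[`, numeric(1), "energy")), 3)
  worse <- mk(-57.02, 9) # within radius, higher energy: rejected
  st3 <- pepforge:::.stack_insert(st2, worse, 200, 0.5)
  expect_equal(length(st3), 2)
  expect_false(any(vapply(st3, `[[`, numeric(1), "energy") == 9))
  # energies stay sorted
  expect_true(!is.unsorted(vapply(st3, `[[`, numeric(1), "energy")))
})

test_that("sampler finds a rigged single-torsion minimum almost surely", {
  # smooth unimodal potential in psi of residue 1; global minimum at +37
  target <- 37
  rig <- function(tor, xyz) {
    d <- (tor[1, 2] - target + 180) %% 360 - 180
    (d / 30)^2
  }
  hits <- 0
  for (s in 1:100) {
    ens <- run_sampling("AA", runs = 1, steps_per_run = 3, init_size = 2,
                        seed = s, energy_fn = rig, minimize_maxit = 40)
    best <- ens$conformations[[1]]
    d <- abs((best$torsions[1, 2] - target + 180) %% 360 - 180)
    if (d < 10) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("sampled low-energy backbones stay mostly in allowed torsion regions", {
  # attainable fraction pinned from reference runs of this heavy-atom
  # model (~0.75; see the methods vignette for why a hydrogen-free model
  # cannot reach the near-total exclusion of positive phi)
  ens <- filter_window(run_sampling("AAAA", runs = 3, steps_per_run = 25,
                                    init_size = 8, seed = 11,
                                    minimize_maxit = 8), 15)
  tor <- do.call(rbind, lapply(ens$conformations, function(cf) cf$torsions))
  frac <- mean(tor[, 1] < 0 | abs(tor[, 1]) > 150)
  expect_gte(frac, 0.60)
})

test_that("embedded minimization never raises the energy", {
  res <- parse_peptide_sequence("AAA")
  tmpl <- build_peptide(res)
  sys <- pepforge:::pep_system(tmpl)
  efun <- function(tor, xyz) pepforge:::sys_energy(sys, xyz)
  set.seed(9)
  for (i in 1:5) {
    tor <- matrix(runif(6, -180, 180), ncol = 2)
    e0 <- efun(tor, pepforge:::build_peptide_xyz(res, tor[, 1],
                                                 tor[, 2])$xyz)
    cf <- pepforge:::.minimize_torsions(res, tor, efun, maxit = 10,
                                        tmpl = tmpl)
    expect_lte(cf$energy, e0 + 1e-9)
  }
})
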