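# Independent oracles and small fixture builders used across the suite.
# Each oracle is implemented from first principles, independently of the
# package code path it checks.

# Monte-Carlo SASA oracle: random points on each solvent sphere, rejection
# against all neighbors. Independent of the deterministic lattice engine.
oracle_sasa <- function(atoms, probe = 1.4, n_points = 10000, seed = 123) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
  r <- radii[atoms$element] + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(atoms)
  set.seed(seed)
  total <- 0
  for (i in seq_len(n)) {
    z <- runif(n_points, -1, 1)
    th <- runif(n_points, 0, 2 * pi)
    rho <- sqrt(1 - z^2)
    p <- cbind(rho * cos(th), rho * sin(th), z) * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      acc <- acc & (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2 > r[j]^2
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

# brute-force free-protein bisection for the direct 1:1 equilibrium
oracle_direct_r <- function(pt, kd, lt, r0 = 0.05, rb = 0.25) {
  vapply(pt, function(p_tot) {
    g <- function(P) P + P * lt / (kd + P) - p_tot
    lo <- 0; hi <- max(p_tot, 1e-30)
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    P <- (lo + hi) / 2
    r0 + (rb - r0) * P / (kd + P)
  }, numeric(1))
}

# brute-force two-ligand competitive equilibrium (bisection on the monotone
# free-protein mass balance)
oracle_competitive <- function(lt, kd1, kd2, pt, lst) {
  g <- function(P) P + P * lst / (kd1 + P) + P * lt / (kd2 + P) - pt
  lo <- rep(0, length(lt)); hi <- rep(pt, length.out = length(lt))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    s <- g(mid) > 0
    hi[s] <- mid[s]; lo[!s] <- mid[!s]
  }
  (lo + hi) / 2
}

# independent Kabsch RMSD (quaternion-free, algebra written from scratch)
oracle_kabsch_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  h <- t(xc) %*% yc
  sv <- svd(h)
  d <- sign(det(sv$v) * det(sv$u))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  dif <- yc - xc %*% t(rot)
  sqrt(mean(rowSums(dif^2)))
}

# minimal atom-row constructor
atom_row <- function(atom, element, x, y, z, resid = "ALA", resno = 1,
                     chain = "A") {
  data.frame(chain = chain, resno = resno, resid = resid, is_d = FALSE,
             atom = atom, element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# random cluster of carbon/oxygen atoms for SASA property tests
random_cluster <- function(n, spread = 4, seed = 1) {
  set.seed(seed)
  el <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i)
    atom_row(paste0("X", i), el[i], runif(1, -spread, spread),
             runif(1, -spread, spread), runif(1, -spread, spread),
             resid = "XXX", resno = i)))
}

# two-atom salt-bridge toy complex (Lys ammonium vs Glu carboxylate)
salt_bridge_complex <- function(sep = 3.2) {
  rec <- rbind(atom_row("CD", "C", -1.25, 0, 0, "GLU"),
               atom_row("OE1", "O", 0, 0, 0, "GLU"),
               atom_row("OE2", "O", -1.86, 1.09, 0, "GLU"))
  pep <- rbind(atom_row("NZ", "N", sep, 0, 0, "LYS", chain = "B"),
               atom_row("CE", "C", sep + 1.47, 0, 0, "LYS", chain = "B"))
  new_complex(rec, pep)
}

# helical peptide stacked above a flat carbon receptor sheet
helix_on_sheet <- function(seq = "AAA", zgap = -6) {
  pep <- build_ideal_helix(seq)
  grid <- expand.grid(x = seq(-2, 8, by = 3), y = seq(-4, 4, by = 3))
  rec <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    atom_row("CB", "C", grid$x[i], grid$y[i], zgap, resno = i)))
  new_complex(rec, pep)
}
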