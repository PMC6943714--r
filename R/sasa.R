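# Solvent-accessible surface area by deterministic sphere-point sampling.
#
# Shrake-Rupley style: each atom's solvent sphere (vdW radius + probe) is
# covered with a fixed spherical-Fibonacci point set; a point is accessible
# if it lies outside every neighboring atom's solvent sphere. Deterministic
# for a fixed point count. Radii: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 A.

#' Solvent-accessible surface area
#'
#' @param atoms atom data.frame with `element, x, y, z` columns (as in a
#'   `ComplexStructure`'s `atoms`), or a `ComplexStructure`
#' @param probe probe radius, Angstrom
#' @param n_points sphere-sampling points per atom
#' @return list of class `SASAResult`: `per_atom_area` (A^2, one entry per
#'   input atom), `total`, `probe_radius`, `n_points`
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  if (inherits(atoms, "ComplexStructure")) atoms <- atoms$atoms
  n <- nrow(atoms)
  stopifnot(n >= 1)
  el <- atoms$element
  if (!all(el %in% names(sasa_radii)))
    stop("no radius for element: ",
         paste(unique(el[!el %in% names(sasa_radii)]), collapse = ", "))
  rad <- sasa_radii[el] + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pts <- fibonacci_sphere(n_points)
  area <- numeric(n)
  # neighbor pruning: pairwise distances once
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  structure(list(per_atom_area = area, total = sum(area),
                 probe_radius = probe, n_points = n_points),
            class = "SASAResult")
}
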