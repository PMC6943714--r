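# Position-specific Ramachandran bias maps.
#
# The map for position n of a sequence is computed by scanning the central
# residue's (phi, psi) over a 10-degree grid in the tripeptide context
# A(n-1)-A(n)-A(n+1) (flanking residues held extended, terminal positions
# use the available neighbor only), Boltzmann-weighting the grid energies
# at a bias temperature, and normalizing. Deriving maps from the energy
# model itself (rather than from database statistics) keeps non-natural and
# D-residues on an equal footing: a D-residue's map is the exact point
# reflection of its L counterpart's because the energy model is mirror
# symmetric.

kB <- 0.0019872041 # kcal/(mol K)

#' Ramachandran bias map for every position of a peptide
#'
#' @param sequence extended-notation string or parsed residue data.frame
#' @param grid_deg grid spacing, degrees (10 by default)
#' @param t_bias bias temperature, K; higher values flatten the map so
#'   minor basins stay populated
#' @param params force-field parameters
#' @return list of class `RamachandranMap`: per position a matrix of
#'   probabilities over (phi, psi) bin centers (rows phi, cols psi), each
#'   summing to 1
#' @export
precompute_rama <- function(sequence, grid_deg = 10, t_bias = 600,
                            params = ff_params()) {
  res <- if (is.character(sequence)) parse_peptide_sequence(sequence) else sequence
  n <- nrow(res)
  centers <- seq(-180 + grid_deg / 2, 180 - grid_deg / 2, by = grid_deg)
  maps <- vector("list", n)
  cache_key <- character(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    sub <- res[lo:hi, , drop = FALSE]
    cache_key[i] <- paste(paste(sub$code, as.integer(sub$is_d), collapse = "|"),
                          i - lo, grid_deg, t_bias)
  }
  store <- .pf_cache$rama
  if (is.null(store)) store <- list()
  for (i in seq_len(n)) {
    if (!is.null(store[[cache_key[i]]])) { maps[[i]] <- store[[cache_key[i]]]; next }
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    sub <- res[lo:hi, , drop = FALSE]
    centre <- i - lo + 1
    en <- matrix(NA_real_, length(centers), length(centers))
    phi <- rep(180, nrow(sub)); psi <- rep(180, nrow(sub))
    sys <- pep_system(build_peptide(sub), params)
    for (a in seq_along(centers)) for (b in seq_along(centers)) {
      phi[centre] <- centers[a]; psi[centre] <- centers[b]
      en[a, b] <- sys_energy(sys, build_peptide_xyz(sub, phi, psi)$xyz)
    }
    w <- exp(-(en - min(en)) / (kB * t_bias))
    maps[[i]] <- w / sum(w)
    store[[cache_key[i]]] <- maps[[i]]
  }
  .pf_cache$rama <- store
  structure(list(maps = maps, centers = centers, grid_deg = grid_deg,
                 t_bias = t_bias), class = "RamachandranMap")
}

# draw one (phi, psi) pair from a position's map (uniform within the bin)
sample_rama <- function(rmap, position) {
  m <- rmap$maps[[position]]
  k <- sample.int(length(m), 1, prob = as.numeric(m))
  a <- (k - 1) %% nrow(m) + 1
  b <- (k - 1) %/% nrow(m) + 1
  g <- rmap$grid_deg
  c(phi = rmap$centers[a] + runif(1, -g / 2, g / 2),
    psi = rmap$centers[b] + runif(1, -g / 2, g / 2))
}
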