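# Toy-complex generator.
#
# Builds synthetic receptor-peptide complexes whose interface descriptors
# are known exactly by construction. Each requested interaction is placed on
# its own "station" along the x axis, stations 25 A apart (far beyond every
# contact cutoff), and each station is rigidly rotated by a seeded random
# rotation so repeated specs with different seeds give different, but
# deterministic, geometry. Counts are verified against the descriptor module
# before returning.

#' Specification for a toy complex
#'
#' @param n_buried_hydrophobic minimum number of buried peptide C/S atoms
#' @param n_hbonds exact number of receptor-peptide hydrogen bonds
#' @param n_salt_bridges exact number of favorable salt-bridge group pairs
#' @param n_like_charge_contacts exact number of repulsive like-charge pairs
#' @param geometry_seed integer seed controlling station orientations
#' @return list of class `ToySpec`
#' @export
toy_spec <- function(n_buried_hydrophobic = 0, n_hbonds = 0,
                     n_salt_bridges = 0, n_like_charge_contacts = 0,
                     geometry_seed = 1L) {
  counts <- c(n_buried_hydrophobic, n_hbonds, n_salt_bridges,
              n_like_charge_contacts)
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(n_buried_hydrophobic = n_buried_hydrophobic,
                 n_hbonds = n_hbonds, n_salt_bridges = n_salt_bridges,
                 n_like_charge_contacts = n_like_charge_contacts,
                 geometry_seed = as.integer(geometry_seed)),
            class = "ToySpec")
}

.toy_row <- function(chain, resno, resid, atom, xyz) {
  data.frame(chain = chain, resno = resno, resid = resid, is_d = FALSE,
             atom = atom, element = substr(atom, 1, 1),
             x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
}

# icosahedron vertices (unit radius)
.icosahedron <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, g), c(0, -1, g), c(0, 1, -g), c(0, -1, -g),
             c(1, g, 0), c(-1, g, 0), c(1, -g, 0), c(-1, -g, 0),
             c(g, 0, 1), c(g, 0, -1), c(-g, 0, 1), c(-g, 0, -1))
  v / sqrt(1 + g^2)
}

#' Generate a toy receptor-peptide complex with known descriptor counts
#'
#' The returned complex, passed to [compute_descriptors()] with default
#' criteria, yields exactly `n_hbonds` hydrogen bonds and a net salt-bridge
#' count of `n_salt_bridges - n_like_charge_contacts`, and at least
#' `n_buried_hydrophobic` buried hydrophobic peptide atoms. Hydrogen-bond
#' stations use a backbone carbonyl acceptor on the receptor and an amide
#' nitrogen donor on the peptide at N...O = 2.9 A, aligned geometry; salt
#' bridges pair Lys NZ with Glu OE1 at 3.2 A; like-charge contacts pair two
#' Lys NZ at 3.5 A; burial encloses a peptide C-beta in an icosahedral cage
#' of receptor methyl carbons at 4.0 A.
#'
#' @param spec a [toy_spec()]
#' @param max_retries placement retries before giving up
#' @return a `ComplexStructure` (capped peptide: no ionized termini)
#' @export
make_toy_complex <- function(spec, max_retries = 5L) {
  stopifnot(inherits(spec, "ToySpec"))
  for (try in seq_len(max_retries)) {
    cs <- .toy_build(spec, salt = spec$geometry_seed + (try - 1L) * 1000003L)
    d <- compute_descriptors(cs, skip_burial = TRUE)
    if (d$XHB == spec$n_hbonds &&
        d$XSB == spec$n_salt_bridges - spec$n_like_charge_contacts)
      return(cs)
  }
  stop("placement failed")
}

.toy_build <- function(spec, salt) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(salt %% .Machine$integer.max)

  rec <- list(); pep <- list()
  ri <- 0L; pi <- 0L; station <- 0L
  add_station <- function(rec_rows, pep_rows) {
    station <<- station + 1L
    origin <- c(25 * station, 0, 0)
    rot <- random_rotation()
    fix <- function(df) {
      xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
      df$x <- xyz[, 1] + origin[1]; df$y <- xyz[, 2] + origin[2]
      df$z <- xyz[, 3] + origin[3]
      df
    }
    if (!is.null(rec_rows)) rec[[length(rec) + 1L]] <<- fix(rec_rows)
    if (!is.null(pep_rows)) pep[[length(pep) + 1L]] <<- fix(pep_rows)
  }

  for (k in seq_len(spec$n_hbonds)) {
    ri <- ri + 1L; pi <- pi + 1L
    # receptor carbonyl: C at -1.23 x, O at origin; peptide N at +2.9 x with
    # its CA behind it so the inferred amide H points straight at O
    r <- rbind(.toy_row("A", ri, "ALA", "C", c(-1.23, 0, 0)),
               .toy_row("A", ri, "ALA", "O", c(0, 0, 0)),
               .toy_row("A", ri, "ALA", "CA", c(-1.95, 1.25, 0)))
    p <- rbind(.toy_row("B", pi, "GLY", "N", c(2.9, 0, 0)),
               .toy_row("B", pi, "GLY", "CA", c(2.9 + 1.458, 0, 0)))
    add_station(r, p)
  }
  for (k in seq_len(spec$n_salt_bridges)) {
    ri <- ri + 1L; pi <- pi + 1L
    r <- rbind(.toy_row("A", ri, "GLU", "CD", c(-1.25, 0, 0)),
               .toy_row("A", ri, "GLU", "OE1", c(0, 0, 0)),
               .toy_row("A", ri, "GLU", "OE2", c(-1.86, 1.09, 0)))
    p <- rbind(.toy_row("B", pi, "LYS", "NZ", c(3.2, 0, 0)),
               .toy_row("B", pi, "LYS", "CE", c(3.2 + 1.47, 0, 0)))
    add_station(r, p)
  }
  for (k in seq_len(spec$n_like_charge_contacts)) {
    ri <- ri + 1L; pi <- pi + 1L
    r <- rbind(.toy_row("A", ri, "LYS", "NZ", c(0, 0, 0)),
               .toy_row("A", ri, "LYS", "CE", c(-1.47, 0, 0)))
    p <- rbind(.toy_row("B", pi, "LYS", "NZ", c(3.5, 0, 0)),
               .toy_row("B", pi, "LYS", "CE", c(3.5 + 1.47, 0, 0)))
    add_station(r, p)
  }
  for (k in seq_len(spec$n_buried_hydrophobic)) {
    pi <- pi + 1L
    p <- rbind(.toy_row("B", pi, "ALA", "CB", c(0, 0, 0)),
               .toy_row("B", pi, "ALA", "CA", c(1.53, 0, 0)))
    cage <- .icosahedron() * 4.0
    r <- do.call(rbind, lapply(seq_len(nrow(cage)), function(j) {
      ri <<- ri + 1L
      rbind(.toy_row("A", ri, "ALA", "CB", cage[j, ]),
            .toy_row("A", ri, "ALA", "CA", cage[j, ] * 5.5 / 4.0))
    }))
    add_station(r, p)
  }
  if (pi == 0L) { # degenerate all-zero spec still needs a peptide
    pi <- pi + 1L
    add_station(NULL, rbind(.toy_row("B", pi, "ALA", "CB", c(0, 0, 0)),
                            .toy_row("B", pi, "ALA", "CA", c(1.53, 0, 0))))
  }
  if (ri == 0L) {
    ri <- ri + 1L
    add_station(rbind(.toy_row("A", ri, "ALA", "CB", c(0, 0, 5)),
                      .toy_row("A", ri, "ALA", "CA", c(1.53, 0, 5))), NULL)
  }
  new_complex(do.call(rbind, rec), do.call(rbind, pep), uncapped = FALSE)
}
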