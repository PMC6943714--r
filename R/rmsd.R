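# Backbone + C-beta RMSD and cluster evaluation helpers.

#' RMSD over backbone and C-beta atoms after optimal superposition
#'
#' Selects N, CA, C, O and CB atoms common to both conformations (matched
#' by residue number and atom name) and returns the Kabsch-superposed RMSD.
#' Including C-beta makes the measure sensitive to side-chain orientation,
#' not just the C-alpha trace.
#'
#' @param conf_a,conf_b atom data.frames (or `DihedralConformation`s)
#' @return RMSD in Angstrom
#' @export
rmsd_bb_cb <- function(conf_a, conf_b) {
  ga <- if (inherits(conf_a, "DihedralConformation")) conf_a$atoms else conf_a
  gb <- if (inherits(conf_b, "DihedralConformation")) conf_b$atoms else conf_b
  sel <- c("N", "CA", "C", "O", "CB")
  ga <- ga[ga$atom %in% sel, ]; gb <- gb[gb$atom %in% sel, ]
  ka <- paste(ga$resno, ga$atom); kb <- paste(gb$resno, gb$atom)
  common <- intersect(ka, kb)
  if (length(common) < 3 || !setequal(ka, kb)) stop("topology mismatch")
  xa <- as.matrix(ga[match(common, ka), c("x", "y", "z")])
  xb <- as.matrix(gb[match(common, kb), c("x", "y", "z")])
  kabsch_rmsd(xa, xb)
}

#' Leader-style clustering of an energy-sorted ensemble
#'
#' Conformations are visited in energy order; each joins the first existing
#' cluster whose representative lies within `radius` (backbone + C-beta
#' RMSD), otherwise it founds a new cluster. Representatives are therefore
#' ranked by energy.
#'
#' @param ensemble a `ConformerEnsemble`
#' @param radius cluster radius, Angstrom
#' @return list of class `ClusterSet`: `representatives` (indices into the
#'   ensemble), `members` (list of index vectors), `radius`
#' @export
cluster_ensemble <- function(ensemble, radius = 1.0) {
  ord <- order(vapply(ensemble$conformations, function(c) c$energy, numeric(1)))
  reps <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (rmsd_bb_cb(ensemble$conformations[[reps[k]]],
                     ensemble$conformations[[i]]) <= radius) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
    }
  }
  structure(list(representatives = reps, members = members, radius = radius),
            class = "ClusterSet")
}

#' Best RMSD to a reference among the top-ranked clusters
#'
#' Minimum backbone + C-beta RMSD between a reference conformation and the
#' representatives of the `top_k` lowest-energy clusters. If fewer clusters
#' exist than `top_k`, all are used.
#'
#' @param clusters a `ClusterSet`
#' @param ensemble the `ConformerEnsemble` the clusters index into
#' @param reference a conformation (atom data.frame) of the same topology
#' @param top_k number of top-ranked clusters to scan (25/100/500 in the
#'   published protocol)
#' @return minimum RMSD, Angstrom
#' @export
min_rmsd_vs_reference <- function(clusters, ensemble, reference, top_k = 25) {
  reps <- head(clusters$representatives, top_k)
  min(vapply(reps, function(i)
    rmsd_bb_cb(ensemble$conformations[[i]], reference), numeric(1)))
}
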