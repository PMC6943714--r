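# Residue templates and force-field parameter tables.
#
# Tables ship as versioned CSV under extdata/params. The residue table lists
# heavy atoms only (X-ray structures of this class lack hydrogens); hydrogen
# counts on donors are implicit and hydrogen positions are generated on
# demand from heavy-atom connectivity. Rows with res == "*" are the shared
# peptide-backbone atoms applied to every residue.

residue_template_table <- function() {
  if (is.null(.pf_cache$res_atoms)) {
    .pf_cache$res_atoms <- read.csv(pf_extdata("params", "residue_atoms.csv"),
                                    stringsAsFactors = FALSE)
  }
  .pf_cache$res_atoms
}

lj_param_table <- function() {
  if (is.null(.pf_cache$lj)) {
    .pf_cache$lj <- read.csv(pf_extdata("params", "lj_params.csv"),
                             stringsAsFactors = FALSE)
  }
  .pf_cache$lj
}

solvation_param_table <- function() {
  if (is.null(.pf_cache$solv)) {
    .pf_cache$solv <- read.csv(pf_extdata("params", "solvation_params.csv"),
                               stringsAsFactors = FALSE)
  }
  .pf_cache$solv
}

#' Atom metadata for one residue type
#'
#' Returns the heavy-atom template (backbone plus side chain) for a residue
#' code: element, bonded heavy neighbors within the residue, implicit
#' hydrogen-donor count, acceptor flag, charged-group membership, partial
#' charge and force-field atom types. Backbone nitrogen of proline carries no
#' donor hydrogen.
#'
#' @param code three-letter residue code (L form; D forms share parameters)
#' @return data.frame, one row per heavy atom
#' @export
residue_template <- function(code) {
  tab <- residue_template_table()
  code <- toupper(code)
  if (!code %in% tab$res && code != "GLY") stop("unknown residue: ", code)
  bb <- tab[tab$res == "*" & tab$atom != "OXT", ]
  side <- tab[tab$res == code, ]
  out <- rbind(bb, side)
  if (code == "GLY") {
    out <- bb
    out$solv_type[out$atom == "CA"] <- "CH2E"
  }
  if (code == "PRO") {
    out$donor[out$atom == "N"] <- 0
    out$parents[out$atom == "N"] <- "CA;CD"
  }
  out$res <- code
  rownames(out) <- NULL
  out
}

known_residues <- function() {
  unique(c(residue_template_table()$res[residue_template_table()$res != "*"],
           "GLY"))
}

# van der Waals radii used for SASA (standard set; H rarely present)
sasa_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# Atom classes of the empirical descriptors: hydrophobic burial counts C and
# S atoms; charged-group burial counts N/O atoms of Asp/Glu/Lys/Arg side
# chains (and ionized termini of uncapped peptides).
charge_class_of <- function(res, atom, element) {
  tab <- residue_template_table()
  cls <- rep("other", length(atom))
  cls[element %in% c("C", "S")] <- "hydrophobic"
  cls[element %in% c("N", "O")] <- "polar"
  key <- paste(res, atom)
  ckey <- paste(tab$res, tab$atom)[tab$charged_group == 1]
  cls[key %in% ckey & element %in% c("N", "O")] <- "charged-group"
  cls
}
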