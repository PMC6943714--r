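# Empirical four-descriptor binding-affinity equation, packing combiner,
# and min-max consensus scoring.

#' Default coefficients of the empirical binding-affinity equation
#'
#' BA = intercept + w_h * dXH + w_c * dXC + w_hb * XHB + w_sb * XSB, with the
#' published signed defaults (-1.94, +0.16, -0.68, -0.52, -0.41), kcal/mol.
#' The coefficients are applied to raw descriptor values as printed; no
#' refitting.
#'
#' @return named numeric vector
#' @export
escore_coefficients <- function() {
  c(intercept = -1.94, w_h = 0.16, w_c = -0.68, w_hb = -0.52, w_sb = -0.41)
}

#' Empirical binding-affinity score of one interface
#'
#' Linear in the four interface descriptors; lower (more negative) means
#' stronger predicted binding, by construction as a binding free energy.
#'
#' @param descriptors an `InterfaceDescriptors` (or list with `dXH`, `dXC`,
#'   `XHB`, `XSB`)
#' @param coeffs coefficient vector as from [escore_coefficients()]
#' @return predicted binding affinity, kcal/mol
#' @export
escore <- function(descriptors, coeffs = escore_coefficients()) {
  d <- c(descriptors$dXH, descriptors$dXC, descriptors$XHB, descriptors$XSB)
  if (!all(is.finite(d))) stop("invalid descriptors")
  unname(coeffs["intercept"] + coeffs["w_h"] * d[1] + coeffs["w_c"] * d[2] +
           coeffs["w_hb"] * d[3] + coeffs["w_sb"] * d[4])
}

#' Fixed-weight packing-score combiner
#'
#' Weighted average of the three packing-normality metrics with published
#' weights: dihedral normality 0.145, 1D distance-dependent packing 0.390,
#' 3D direction-dependent packing 0.465.
#'
#' @param metrics a `PackingMetrics` (or list/numeric of the three values in
#'   that order)
#' @param weights numeric length 3, must sum to 1
#' @return combined packing score
#' @export
packing_score <- function(metrics, weights = c(0.145, 0.390, 0.465)) {
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  m <- if (is.numeric(metrics)) metrics
  else c(metrics$dihedral_normality, metrics$packing1d_normality,
         metrics$packing3d_normality)
  stopifnot(length(m) == 3, all(is.finite(m)))
  sum(weights * m)
}

#' Construct a score vector for consensus scoring
#'
#' @param method method name
#' @param values named numeric vector (peptide id -> score)
#' @param orientation `"lower_better"` (e.g. binding free energies) or
#'   `"higher_better"`
#' @return list of class `ScoreVector`
#' @export
score_vector <- function(method, values, orientation = c("lower_better",
                                                         "higher_better")) {
  orientation <- match.arg(orientation)
  stopifnot(length(values) >= 1, !is.null(names(values)))
  structure(list(method = method, values = values, orientation = orientation),
            class = "ScoreVector")
}

#' Min-max consensus score across methods
#'
#' Each score vector is min-max normalized respecting its orientation (best
#' score -> 1, worst -> 0); the consensus is the arithmetic mean of the
#' normalized scores per peptide. Constant vectors are rejected (silent
#' midpoints would corrupt consensus ranks).
#'
#' @param score_vectors list of [score_vector()] objects covering identical
#'   peptide ids
#' @return named numeric vector of consensus scores in `[0, 1]`
#' @export
consensus <- function(score_vectors) {
  stopifnot(length(score_vectors) >= 1)
  ids <- sort(names(score_vectors[[1]]$values))
  if (length(ids) < 2) stop("need >= 2 peptides for min-max normalization")
  norm <- sapply(score_vectors, function(sv) {
    stopifnot(inherits(sv, "ScoreVector"))
    if (!identical(sort(names(sv$values)), ids))
      stop("score vectors cover different peptide ids")
    v <- sv$values[ids]
    rng <- range(v)
    if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2])))
      stop("degenerate score range in method ", sv$method)
    u <- (v - rng[1]) / diff(rng)
    if (sv$orientation == "lower_better") u <- 1 - u
    u
  })
  out <- rowMeans(as.matrix(norm))
  names(out) <- ids
  out
}
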