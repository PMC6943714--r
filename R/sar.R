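# Structure-activity arithmetic and statistics over the bundled published
# tables.
#
# Two fixtures ship as versioned CSV transcriptions of the printed tables:
# the conformational-sampling summary (16 peptide systems: minimum
# low-energy RMSD to the X-ray conformation, cluster counts at 1.0 A, and
# the best RMSD within the top 25/100/500 ranked clusters) and the
# prospective Ala-/D-scan of the stapled ATSP-7041 analog against MDM2/MDMX
# (measured Kd and ddG plus the three calculated ddG columns). A checksum
# test guards the transcriptions against drift.
#
# Unit note: the thermal energy RT is 0.593 kcal/mol at 298 K. The printed
# experimental MDM2 ddG column of the prospective table is internally
# consistent with ddG = RT ln(Kd/Kd_WT) only for an effective RT of about
# 0.815 kcal/mol, while the MDMX column matches 0.593; both constants are
# exposed and the discrepancy is surfaced to users rather than resolved.
# Correlation statistics are unaffected: Pearson r is invariant under
# positive affine maps, so the choice of RT never moves an r^2.

#' Thermal-energy constants (kcal/mol)
#' @export
rt_standard <- 0.593

#' @rdname rt_standard
#' @export
rt_table4_mdm2_effective <- 0.815

#' Relative binding free energy from dissociation constants
#'
#' `ddG = RT * ln(kd / kd_ref)`.
#'
#' @param kd,kd_ref dissociation constants (same units, conventionally nM)
#' @param rt thermal energy, kcal/mol
#' @return ddG, kcal/mol
#' @export
kd_to_ddg <- function(kd, kd_ref, rt = rt_standard) {
  if (any(!is.finite(kd)) || any(!is.finite(kd_ref)) ||
      any(kd <= 0) || any(kd_ref <= 0)) stop("kd values must be positive")
  rt * log(kd / kd_ref)
}

#' pKd from a dissociation constant in nM
#' @param kd_nM dissociation constant, nM
#' @return -log10(Kd in molar)
#' @export
pkd_from_kd <- function(kd_nM) {
  if (any(kd_nM <= 0)) stop("kd values must be positive")
  -log10(kd_nM * 1e-9)
}

#' Assign a floor score to inactive peptides
#'
#' Peptides reported only as qualitatively inactive carry no Kd; to keep
#' them in correlations their binding-energy value is set to a fixed floor
#' (published choice: -2.0 kcal/mol, applied to the binding-energy axis).
#'
#' @param records data.frame with logical column `active` and a value
#'   column named by `column`
#' @param floor floor value, kcal/mol
#' @param column name of the binding-energy column to floor
#' @return list: `records` (modified) and `n_modified`
#' @export
assign_inactive_floor <- function(records, floor = -2.0, column = "energy") {
  stopifnot(is.data.frame(records), "active" %in% names(records),
            column %in% names(records))
  sel <- !records$active & (is.na(records[[column]]) |
                              records[[column]] != floor)
  records[[column]][!records$active] <- floor
  list(records = records, n_modified = sum(sel))
}

#' Pearson correlation with r-squared
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return list of class `CorrelationResult`: `n`, `r`, `r2`
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  r <- cor(x, y)
  structure(list(n = length(x), r = r, r2 = r^2), class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("CorrelationResult: n=%d r=%.3f r2=%.3f\n", x$n, x$r, x$r2))
  invisible(x)
}

#' Two-term ordinary least squares (length + staple indicator)
#'
#' OLS with intercept of `y` on peptide length and a staple indicator;
#' returns the coefficient of determination. A rank-deficient design is an
#' error rather than a silent drop.
#'
#' @param x1 peptide lengths
#' @param x2 staple indicator (0/1)
#' @param y response (minimum RMSD)
#' @return list: `r2`, `fit` (the lm object)
#' @export
ols_two_term <- function(x1, x2, y) {
  stopifnot(length(x1) == length(y), length(x2) == length(y), length(y) >= 4)
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3) stop("rank-deficient design")
  fit <- lm(y ~ x1 + x2)
  list(r2 = summary(fit)$r.squared, fit = fit)
}

#' Bundled fixture of the conformational-sampling summary table
#' @return data.frame (16 rows)
#' @export
table2_fixture <- function() {
  df <- read.csv(pf_extdata("tables", "table2_sampling.csv"),
                 stringsAsFactors = FALSE)
  df$stapled <- as.integer(grepl("Stapled", df$description))
  df
}

#' Bundled fixture of the prospective Ala-/D-scan table
#' @return data.frame (WT + 10 Ala-scan + 12 D-scan rows)
#' @export
table4_fixture <- function() {
  read.csv(pf_extdata("tables", "table4_prospective.csv"),
           stringsAsFactors = FALSE)
}

#' Summary statistics of the sampling-results fixture
#'
#' Column means of the minimum RMSD and the best-within-top-k RMSDs, the
#' Pearson correlation between peptide length and minimum RMSD, and the
#' two-term (length + staple) regression R^2.
#'
#' @param fixture data.frame as from [table2_fixture()]
#' @return list: `mean_min_rmsd`, `mean_best25`, `mean_best100`,
#'   `mean_best500`, `r_length_rmsd`, `r2_two_term`
#' @export
table2_stats <- function(fixture = table2_fixture()) {
  need <- c("n_aa", "min_rmsd", "best25", "best100", "best500", "stapled")
  if (!all(need %in% names(fixture)) || nrow(fixture) != 16)
    stop("fixture incomplete")
  list(mean_min_rmsd = mean(fixture$min_rmsd),
       mean_best25 = mean(fixture$best25),
       mean_best100 = mean(fixture$best100),
       mean_best500 = mean(fixture$best500),
       r_length_rmsd = pearson(fixture$n_aa, fixture$min_rmsd)$r,
       r2_two_term = ols_two_term(fixture$n_aa, fixture$stapled,
                                  fixture$min_rmsd)$r2)
}

#' Prospective-scan correlations by method
#'
#' r^2 of each calculated ddG column against the experimental MDM2 ddG,
#' separately for the Ala scan (10 mutants) and the D scan (12 mutants).
#' The wild type carries no ddG and is excluded by default (set
#' `include_wt` to add it at (0, 0)).
#'
#' @param fixture data.frame as from [table4_fixture()]
#' @param include_wt logical
#' @return named list `(scan).(method)` of `CorrelationResult`s
#' @export
table4_correlations <- function(fixture = table4_fixture(),
                                include_wt = FALSE) {
  methods <- c(escore = "ddg_escore", yscore = "ddg_yscore",
               boltzmann = "ddg_boltzmann")
  if (!all(c("scan", "ddg_mdm2", methods) %in% names(fixture)))
    stop("missing column")
  out <- list()
  for (scan in c("ala", "d")) {
    rows <- fixture[fixture$scan == scan, ]
    for (m in names(methods)) {
      x <- rows[[methods[[m]]]]; y <- rows$ddg_mdm2
      if (include_wt) { x <- c(x, 0); y <- c(y, 0) }
      out[[paste(scan, m, sep = ".")]] <- pearson(x, y)
    }
  }
  out
}
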