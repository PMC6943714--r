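# Fluorescence-anisotropy binding models, Kd fitting and simulation.
#
# Direct 1:1 titration: the bound fraction of the labeled peptide has the
# exact quadratic closed form
#   fb = [(Kd + Lt + Pt) - sqrt((Kd + Lt + Pt)^2 - 4 Lt Pt)] / (2 Lt)
# and r = r0 + (rb - r0) * fb. Competitive titration (labeled peptide at
# Lst, unlabeled competitor at Lt, protein at Pt): the free-protein
# concentration is the physical root of a cubic; with
#   d = Kd1 + Kd2 + Lst + Lt - Pt
#   e = (Lt - Pt) Kd1 + (Lst - Pt) Kd2 + Kd1 Kd2
#   f = -Kd1 Kd2 Pt
#   theta = arccos[(-2 d^3 + 9 d e - 27 f) / (2 sqrt((d^2 - 3 e)^3))]
# the free protein is P = [2 sqrt(d^2 - 3 e) cos(theta/3) - d] / 3 and the
# bound labeled fraction is P / (Kd1 + P). Both closed forms are checked in
# the test suite against brute-force equilibrium solvers (bisection on the
# monotone mass balance) to 1e-9.
#
# Concentrations are molar throughout.

#' Direct 1:1 anisotropy model
#'
#' @param pt total protein, M (may be a vector: the titration axis)
#' @param kd dissociation constant, M
#' @param lt total labeled peptide, M
#' @param r0,rb anisotropy of the free and the bound labeled peptide
#' @return anisotropy value(s)
#' @export
direct_anisotropy <- function(pt, kd, lt, r0 = 0.05, rb = 0.25) {
  if (any(lt <= 0)) stop("lt must be positive")
  stopifnot(kd > 0, all(pt >= 0))
  s <- kd + lt + pt
  fb <- (s - sqrt(pmax(s^2 - 4 * lt * pt, 0))) / (2 * lt)
  fb <- pmin(pmax(fb, 0), 1)
  r0 + (rb - r0) * fb
}

#' Exact competitive anisotropy model
#'
#' @param lt total unlabeled competitor, M (may be a vector)
#' @param kd1 labeled-peptide/protein Kd, M
#' @param kd2 competitor/protein Kd, M
#' @param pt total protein, M
#' @param lst total labeled peptide, M
#' @param r0,rb anisotropy endpoints
#' @param warn warn when the assay assumption `pt > lst` is violated
#'   (computation proceeds)
#' @return anisotropy value(s)
#' @export
competitive_anisotropy <- function(lt, kd1, kd2, pt, lst, r0 = 0.05,
                                   rb = 0.25, warn = TRUE) {
  stopifnot(kd1 > 0, kd2 > 0, pt >= 0, lst > 0, all(lt >= 0))
  if (warn && pt <= lst)
    warning("assay assumption violated: total protein <= labeled peptide")
  d <- kd1 + kd2 + lst + lt - pt
  e <- (lt - pt) * kd1 + (lst - pt) * kd2 + kd1 * kd2
  f <- -kd1 * kd2 * pt
  q <- d^2 - 3 * e
  arg <- (-2 * d^3 + 9 * d * e - 27 * f) / (2 * sqrt(q^3))
  if (any(abs(arg) > 1 + 1e-9)) stop("cubic discriminant out of range")
  theta <- acos(pmin(1, pmax(-1, arg)))
  p_free <- (2 * sqrt(q) * cos(theta / 3) - d) / 3
  # The trigonometric root loses precision when theta approaches the ends
  # of its range (catastrophic cancellation for extreme parameter ratios).
  # Polish on the equivalent monotone free-protein mass balance
  #   g(P) = P + P*Lst/(Kd1+P) + P*Lt/(Kd2+P) - Pt
  # with safeguarded, clamped Newton steps seeded by the closed form.
  p_free <- pmin(pmax(p_free, 0), pt)
  for (it in 1:8) {
    g <- p_free + p_free * lst / (kd1 + p_free) +
      p_free * lt / (kd2 + p_free) - pt
    gp <- 1 + lst * kd1 / (kd1 + p_free)^2 + lt * kd2 / (kd2 + p_free)^2
    p_free <- pmin(pmax(p_free - g / gp, 0), pt)
  }
  fb <- p_free / (kd1 + p_free)
  fb <- pmin(pmax(fb, 0), 1)
  r0 + (rb - r0) * fb
}

#' Simulate a titration experiment
#'
#' Evaluates the chosen model over a concentration series and adds Gaussian
#' noise, replicate by replicate (triplicate by default, matching common
#' assay practice).
#'
#' @param model `"direct"` or `"competitive"`
#' @param conc titrant concentration series, M (protein for direct,
#'   competitor for competitive)
#' @param pars named list of model parameters (direct: kd, lt, r0, rb;
#'   competitive: kd1, kd2, pt, lst, r0, rb)
#' @param sigma Gaussian noise standard deviation (anisotropy units)
#' @param replicates number of replicates
#' @param seed integer seed (deterministic per seed)
#' @return data.frame of class `TitrationCurve`: `conc_M`, `anisotropy`,
#'   `replicate`, with attributes `model`, `pars`, `sigma`
#' @export
simulate_titration <- function(model = c("direct", "competitive"), conc,
                               pars, sigma = 0.005, replicates = 3,
                               seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(conc) >= 1, all(conc >= 0))
  mu <- if (model == "direct") {
    direct_anisotropy(conc, pars$kd, pars$lt,
                      pars$r0 %||% 0.05, pars$rb %||% 0.25)
  } else {
    competitive_anisotropy(conc, pars$kd1, pars$kd2, pars$pt, pars$lst,
                           pars$r0 %||% 0.05, pars$rb %||% 0.25, warn = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(replicates), function(rep) {
    data.frame(conc_M = conc,
               anisotropy = mu + rnorm(length(conc), 0, sigma),
               replicate = rep)
  }))
  structure(out, model = model, pars = pars, sigma = sigma,
            class = c("TitrationCurve", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# replicate-variance weights (weighted LS when replicates >= 2)
.curve_weights <- function(curve) {
  if (length(unique(curve$replicate)) < 2) return(rep(1, nrow(curve)))
  v <- tapply(curve$anisotropy, curve$conc_M, var)
  v[!is.finite(v) | v <= 0] <- median(v[is.finite(v) & v > 0], na.rm = TRUE)
  if (all(!is.finite(v))) return(rep(1, nrow(curve)))
  w <- 1 / v[as.character(curve$conc_M)]
  as.numeric(w / mean(w))
}

#' Fit the direct 1:1 anisotropy model
#'
#' Nonlinear least squares (Levenberg-Marquardt) for `r0`, `rb` and `kd`
#' with the labeled-peptide concentration fixed. Kd is fitted on the log
#' scale. Weighted by per-concentration replicate variance when replicates
#' are available.
#'
#' @param curve data.frame with `conc_M` (protein) and `anisotropy`
#'   (optionally `replicate`)
#' @param lt fixed total labeled peptide, M
#' @param start optional named start values (kd, r0, rb)
#' @return object of class `anisofit`: coefficients, standard errors,
#'   `converged`, residuals, the underlying nls fit
#' @export
fit_direct <- function(curve, lt, start = NULL) {
  if (length(unique(curve$conc_M)) < 5)
    stop("degenerate design: need >= 5 distinct concentrations")
  if (is.null(curve$replicate)) curve$replicate <- 1L
  w <- .curve_weights(curve)
  st <- list(log_kd = log(start$kd %||% stats::median(curve$conc_M[curve$conc_M > 0])),
             r0 = start$r0 %||% min(curve$anisotropy),
             rb = start$rb %||% max(curve$anisotropy))
  fit <- minpack.lm::nlsLM(
    anisotropy ~ direct_anisotropy(conc_M, exp(log_kd), lt, r0, rb),
    data = curve, start = st, weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  .anisofit(fit, kind = "direct", extra = list(lt = lt))
}

#' Fit the competitive anisotropy model for a competitor Kd
#'
#' `kd1` (labeled peptide), `pt` and `lst` are fixed by the assay design;
#' `kd2`, `r0` and `rb` are estimated. Flags a fitted floor below the
#' free-peptide anisotropy (which would indicate an unintended
#' ligand-labeled-peptide interaction) and an unidentifiable `kd2` (no
#' displacement over the design range).
#'
#' @param curve data.frame with `conc_M` (competitor) and `anisotropy`
#' @param kd1 labeled-peptide Kd, M (e.g. the reported 13.0 nM reference)
#' @param pt,lst fixed protein / labeled-peptide totals, M (assay defaults
#'   250 nM and 50 nM)
#' @param start optional named start values (kd2, r0, rb)
#' @param r0_free independently measured anisotropy of the free labeled
#'   peptide (the no-protein control); when given, a final baseline below
#'   it is flagged, since that indicates an unintended interaction between
#'   the competitor and the labeled peptide
#' @return object of class `anisofit`, with `flags` listing assumption
#'   violations
#' @export
fit_competitive <- function(curve, kd1, pt = 250e-9, lst = 50e-9,
                            start = NULL, r0_free = NULL) {
  if (length(unique(curve$conc_M)) < 6)
    stop("degenerate design: need >= 6 competitor concentrations")
  if (is.null(curve$replicate)) curve$replicate <- 1L
  w <- .curve_weights(curve)
  st <- list(log_kd2 = log(start$kd2 %||% kd1),
             r0 = start$r0 %||% min(curve$anisotropy),
             rb = start$rb %||% max(curve$anisotropy))
  fit <- minpack.lm::nlsLM(
    anisotropy ~ competitive_anisotropy(conc_M, kd1, exp(log_kd2), pt, lst,
                                        r0, rb, warn = FALSE),
    data = curve, start = st, weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  out <- .anisofit(fit, kind = "competitive",
                   extra = list(kd1 = kd1, pt = pt, lst = lst))
  flags <- character(0)
  if (pt <= lst) flags <- c(flags, "assay assumption violated: pt <= lst")
  if (!is.null(r0_free)) {
    top <- curve$conc_M >= max(curve$conc_M)
    baseline <- mean(curve$anisotropy[top])
    tol <- max(3 * (out$sigma %||% 0), 1e-3)
    if (baseline < r0_free - tol)
      flags <- c(flags, "final baseline below free-peptide anisotropy")
  }
  se_log <- out$se[["log_kd2"]]
  if (!is.finite(se_log) || se_log > 3)
    flags <- c(flags, "kd2 unidentifiable over the design range")
  out$flags <- flags
  out
}

.anisofit <- function(fit, kind, extra) {
  s <- summary(fit)
  co <- coef(fit)
  se <- s$coefficients[, "Std. Error"]
  kdname <- if (kind == "direct") "kd" else "kd2"
  logname <- paste0("log_", kdname)
  est <- c(setNames(exp(co[[logname]]), kdname),
           co[setdiff(names(co), logname)])
  se_kd <- exp(co[[logname]]) * se[[logname]] # delta method
  structure(list(kind = kind, coefficients = est,
                 se = c(setNames(se_kd, kdname), se),
                 sigma = s$sigma,
                 converged = fit$convInfo$isConv %||% TRUE,
                 residuals = residuals(fit), fit = fit, extra = extra,
                 flags = character(0)),
            class = "anisofit")
}

#' @export
print.anisofit <- function(x, ...) {
  kdname <- if (x$kind == "direct") "kd" else "kd2"
  cat(sprintf("Anisotropy fit (%s model): %s = %.4g M (SE %.2g)\n", x$kind,
              kdname, x$coefficients[[kdname]], x$se[[kdname]]))
  others <- setdiff(names(x$coefficients), kdname)
  cat("  ", paste(sprintf("%s = %.4g", others, x$coefficients[others]),
                  collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.anisofit <- function(object, ...) object$coefficients

#' @export
summary.anisofit <- function(object, ...) {
  data.frame(term = names(object$coefficients),
             estimate = unname(object$coefficients),
             std_error = unname(object$se[names(object$coefficients)]))
}

#' @export
predict.anisofit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit)
  else predict(object$fit, newdata = newdata)
}

#' @export
residuals.anisofit <- function(object, ...) object$residuals
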