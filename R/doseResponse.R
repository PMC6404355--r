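# four-parameter logistic: V(d) = bottom + (top-bottom)/(1 + (d/ic50)^hill),
# parameterized in log10(ic50); d = 0 maps to the top asymptote
.fourPL <- function(d, top, bottom, logIC50, hill) {
  frac <- ifelse(d > 0, 1 / (1 + 10^(hill * (log10(pmax(d, .Machine$double.xmin)) - logIC50))), 1)
  bottom + (top - bottom) * frac
}

#' Evaluate a four-parameter-logistic viability curve
#'
#' @param d dose(s), >= 0; dose 0 returns \code{top}.
#' @param top,bottom asymptotes (\% viability).
#' @param ic50 half-maximal inhibitory concentration (> 0).
#' @param hill Hill slope (> 0).
#' @return predicted viability, same length as \code{d}.
#' @examples
#' fourPL(c(0, 10, 1e6), top = 100, bottom = 0, ic50 = 10, hill = 2)
#' @export
fourPL <- function(d, top = 100, bottom = 0, ic50, hill = 1) {
  .assert(all(d >= 0), "doses must be non-negative")
  .assert(ic50 > 0, "ic50 must be positive")
  .assert(hill > 0, "hill must be positive")
  .fourPL(d, top, bottom, log10(ic50), hill)
}

.validateViabilityTable <- function(tbl) {
  .assert(is.data.frame(tbl) && all(c("dose", "viability") %in% names(tbl)),
          "need a data.frame with columns 'dose' and 'viability'")
  .assert(all(is.finite(tbl$viability)), "viabilities must be finite")
  .assert(all(tbl$dose >= 0), "doses must be non-negative")
  nz <- unique(tbl$dose[tbl$dose > 0])
  .assert(length(nz) >= 4,
          "need at least 4 distinct nonzero doses for a 4PL fit")
  invisible(tbl)
}

# starting values per the standard recipe: top from the two lowest doses,
# bottom from the two highest, ic50 bracketing 50% response by
# interpolation, hill = 1
.startValues <- function(dose, viab) {
  ud <- sort(unique(dose))
  meanAt <- vapply(ud, function(d) mean(viab[dose == d]), numeric(1))
  top0 <- mean(meanAt[seq_len(min(2, length(ud)))])
  bottom0 <- mean(meanAt[seq(length(ud) - min(2, length(ud)) + 1,
                             length(ud))])
  if (bottom0 >= top0) { top0 <- max(meanAt); bottom0 <- min(meanAt) }
  half <- (top0 + bottom0) / 2
  nz <- ud[ud > 0]
  mnz <- meanAt[match(nz, ud)]
  below <- which(mnz <= half)
  logIC50 <- if (length(below) && below[1] > 1) {
    i <- below[1]
    # linear interpolation in log-dose across the 50% crossing
    w <- (mnz[i - 1] - half) / (mnz[i - 1] - mnz[i])
    (1 - w) * log10(nz[i - 1]) + w * log10(nz[i])
  } else {
    log10(stats::median(nz))
  }
  c(top = top0, bottom = bottom0, logIC50 = logIC50, hill = 1)
}

# Heteroscedasticity-consistent (HC3) standard error of log10(IC50).
# Viability noise clipped at zero is not homoscedastic Gaussian: tail-dose
# residuals have reduced variance, so the pooled residual variance
# understates the noise in the informative mid-dose region and the naive
# (JtJ)^-1 s^2 covariance undercovers. The sandwich estimator with
# leverage-adjusted residuals e_i/(1-h_ii) (HC3, the small-sample
# recommendation) is robust to this.
.sandwichSELogIC50 <- function(dose, viab, est) {
  p0 <- unlist(est[c("top", "bottom", "logIC50", "hill")])
  pred <- function(p) .fourPL(dose, p[1], p[2], p[3], p[4])
  n <- length(viab)
  J <- matrix(0, n, 4)
  for (j in 1:4) {
    h <- max(1e-6, 1e-6 * abs(p0[j]))
    up <- p0; up[j] <- up[j] + h
    dn <- p0; dn[j] <- dn[j] - h
    J[, j] <- (pred(up) - pred(dn)) / (2 * h)
  }
  e <- viab - pred(p0)
  bread <- tryCatch(solve(crossprod(J)), error = function(x) NULL)
  if (is.null(bread)) return(NA_real_)
  lev <- rowSums((J %*% bread) * J)
  eAdj <- e / pmax(1 - lev, 0.1)
  meat <- crossprod(J * eAdj)
  vc <- bread %*% meat %*% bread
  if (vc[3, 3] < 0) return(NA_real_)
  sqrt(vc[3, 3])
}

#' Fit a four-parameter-logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{V(d) = bottom + (top - bottom)/(1 + (d/IC_{50})^{hill})}
#' to replicate viability data, parameterized in log10(IC50) with the Hill
#' slope constrained positive. The 95\% confidence interval for the IC50
#' uses a heteroscedasticity-consistent (sandwich) standard error for
#' log10(IC50) with a t-quantile at the residual degrees of freedom;
#' viability that is clipped at 0\% (as CCK-8 readouts effectively are)
#' makes the classical equal-variance covariance undercover. The same
#' standard error feeds the IC50-shift z-test. Non-convergence is flagged
#' on the returned object, never silent.
#'
#' @param table data.frame with columns \code{dose} and \code{viability}
#'   (\% of untreated control); replicate rows share a dose. Needs at least
#'   4 distinct nonzero doses. Extra columns are ignored, so the tables
#'   written by [genDoseResponse()] can be passed directly.
#' @param level confidence level for the IC50 interval (default 0.95).
#' @return a [FourPLFit-class].
#' @examples
#' d <- 200 / 2^(0:7)
#' tbl <- data.frame(dose = d, viability = fourPL(d, ic50 = 51, hill = 2))
#' fit4PL(tbl)
#' @export
fit4PL <- function(table, level = 0.95) {
  .validateViabilityTable(table)
  dose <- table$dose
  viab <- table$viability
  start <- .startValues(dose, viab)
  rssOf <- function(p) {
    sum((viab - .fourPL(dose, p[1], p[2], p[3], p[4]))^2)
  }
  est <- NULL; hess <- NULL; note <- ""
  fit <- tryCatch(
    nls(viab ~ .fourPL(dose, top, bottom, logIC50, hill),
        start = as.list(start), algorithm = "port",
        lower = c(top = -Inf, bottom = -Inf, logIC50 = -Inf, hill = 1e-3),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- coef(fit)
    conv <- TRUE
  } else {
    # fall back to direct RSS minimisation (also covers noise-free data,
    # where nls refuses to iterate on a zero-residual problem)
    opt <- optim(start, rssOf, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    opt <- optim(opt$par, rssOf, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    est <- opt$par
    note <- "nls failed; parameters from direct RSS minimisation"
    conv <- opt$convergence == 0
  }
  if (!is.finite(est[["hill"]]) || est[["hill"]] <= 0) {
    conv <- FALSE; note <- "non-positive hill slope"
  }
  rss <- rssOf(est)
  dfres <- length(viab) - 4
  ic50hat <- 10^est[["logIC50"]]
  seLog <- .sandwichSELogIC50(dose, viab, est)
  if (rss < 1e-12 * max(1, sum(viab^2))) seLog <- 0  # exact-data degenerate
  ciLog <- if (is.finite(seLog)) {
    est[["logIC50"]] + c(-1, 1) * qt(1 - (1 - level) / 2, dfres) * seLog
  } else {
    conv <- FALSE
    if (!nzchar(note)) note <- "singular covariance; no CI available"
    c(NA_real_, NA_real_)
  }
  new("FourPLFit",
      top = unname(est[["top"]]), bottom = unname(est[["bottom"]]),
      hill = unname(est[["hill"]]), ic50 = unname(ic50hat),
      ic50CI = unname(10^ciLog), logIC50SE = unname(seLog),
      rss = rss, df = as.numeric(dfres), converged = conv, message = note)
}

#' Test a shift between two IC50s
#'
#' Two-sided z-test on the difference of log10(IC50)s using the asymptotic
#' standard errors of two independent 4PL fits: the working substitute for
#' the published per-drug significance stars, whose exact test was not
#' stated.
#'
#' @param a,b converged [FourPLFit-class] objects (a = untreated,
#'   b = treated, by convention).
#' @param alpha significance level (default 0.05).
#' @return a list with \code{ratio} (a/b on the IC50 scale), \code{z},
#'   \code{p} and \code{significant}.
#' @examples
#' d <- 50 / 2^(0:7)
#' f1 <- fit4PL(data.frame(dose = d,
#'   viability = fourPL(d, ic50 = 12.5, hill = 2) + rnorm(8)))
#' f2 <- fit4PL(data.frame(dose = d,
#'   viability = fourPL(d, ic50 = 0.8, hill = 2) + rnorm(8)))
#' compareIC50(f1, f2)
#' @export
compareIC50 <- function(a, b, alpha = 0.05) {
  .assert(is(a, "FourPLFit") && is(b, "FourPLFit"),
          "inputs must be FourPLFit objects")
  .assert(isConverged(a) && isConverged(b),
          "both fits must have converged")
  la <- log10(ic50(a)); lb <- log10(ic50(b))
  seDiff <- sqrt(a@logIC50SE^2 + b@logIC50SE^2)
  if (seDiff == 0) {
    z <- if (la == lb) 0 else sign(la - lb) * Inf
  } else {
    z <- (la - lb) / seDiff
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  list(ratio = ic50(a) / ic50(b), z = z, p = p,
       significant = p < alpha)
}

# Fig-1-calibrated fold inductions at 9 uM CHIR: CYP1A2 20x, CYP2E1 and
# CYP3A4 5x, CYP2B6 unchanged. Intermediate points are configurable by the
# caller; only the 0 and 9 uM anchors are asserted.
.inductionAnchors <- list(
  CYP1A2 = 20, CYP2E1 = 5, CYP3A4 = 5, CYP2B6 = 1
)

#' CHIR-to-fold-induction calibration curve for a CYP
#'
#' Builds the calibration used throughout the package: fold induction of
#' the CYP mRNA as a function of CHIR concentration, anchored at
#' (0 uM, 1-fold) and at the published 9 uM maxima (CYP1A2 20-fold,
#' CYP2E1/CYP3A4 5-fold, CYP2B6 unchanged). Additional interior points
#' (e.g. at 3 and 6 uM) may be supplied.
#'
#' @param cyp one of \code{"CYP1A2"}, \code{"CYP2E1"}, \code{"CYP3A4"},
#'   \code{"CYP2B6"}.
#' @param chir,fold optional extra calibration points (uM, fold); merged
#'   with the 0 and 9 uM anchors.
#' @return an [InductionCurve-class].
#' @examples
#' inductionCurve("CYP1A2")
#' @export
inductionCurve <- function(cyp = c("CYP1A2", "CYP2E1", "CYP3A4", "CYP2B6"),
                           chir = numeric(0), fold = numeric(0)) {
  cyp <- match.arg(cyp)
  pts <- data.frame(chir = c(0, chir, 9),
                    fold = c(1, fold, .inductionAnchors[[cyp]]))
  pts <- pts[!duplicated(pts$chir), , drop = FALSE]
  pts <- pts[order(pts$chir), , drop = FALSE]
  new("InductionCurve", cyp = cyp, chir = pts$chir, fold = pts$fold)
}

#' Interpolate fold induction at a CHIR concentration
#'
#' Piecewise log-linear interpolation of fold induction between the
#' calibration points (linear in log fold vs CHIR), clamped at the last
#' calibrated point beyond the range. The midpoint between two points is
#' therefore their geometric mean.
#'
#' @param curve an [InductionCurve-class].
#' @param chir CHIR concentration(s) in uM, >= 0.
#' @return fold induction, same length as \code{chir}.
#' @examples
#' inductionAt(inductionCurve("CYP1A2"), c(0, 4.5, 9, 12))
#' @export
inductionAt <- function(curve, chir) {
  .assert(is(curve, "InductionCurve"), "curve must be an InductionCurve")
  .assert(all(chir >= 0), "CHIR concentration must be non-negative")
  chirC <- pmin(pmax(chir, min(curve@chir)), max(curve@chir))
  lf <- approx(curve@chir, log(curve@fold), xout = chirC)$y
  exp(lf)
}

#' Normalize CYP activity to cell number
#'
#' Divides P450-Glo luminescence by CCK-8 absorbance so that activity is
#' expressed per viable cell, optionally rescaled relative to a control
#' condition's ratio.
#'
#' @param luminescence P450-Glo luminescence values (a.u.).
#' @param absorbance CCK-8 absorbance values (a.u., > 0), recycled.
#' @param control optional control ratio (or c(luminescence, absorbance)
#'   pair) to express activity relative to.
#' @return normalized activity (a.u./a.u.), relative if \code{control}
#'   given.
#' @examples
#' normalizeCypActivity(2400, 1.2, control = c(800, 0.8))  # 2.0
#' @export
normalizeCypActivity <- function(luminescence, absorbance, control = NULL) {
  .assert(all(is.finite(absorbance)) && all(absorbance > 0),
          "absorbance must be strictly positive")
  act <- luminescence / absorbance
  if (!is.null(control)) {
    ctrl <- if (length(control) == 2) control[1] / control[2] else control
    .assert(is.finite(ctrl) && ctrl > 0, "invalid control ratio")
    act <- act / ctrl
  }
  act
}
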