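#' @useDynLib hepaZone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Describe a diffusing solute
#'
#' @param name solute name.
#' @param molecularWeight molecular weight in g/mol (> 0).
#' @return a list with class \code{"SoluteDescriptor"}.
#' @examples
#' soluteDescriptor("CHIR99021", 465.34)
#' @export
soluteDescriptor <- function(name, molecularWeight) {
  .assert(is.numeric(molecularWeight) && molecularWeight > 0,
          "molecularWeight must be strictly positive")
  structure(list(name = name, molecularWeight = molecularWeight),
            class = "SoluteDescriptor")
}

#' Reference diffusion measurement for a tracer solute
#'
#' The canonical reference is rhodamine B (479 g/mol), whose diffusion
#' coefficient in 1\% agarose is about 2.96e-6 cm^2/s.
#'
#' @param solute a [soluteDescriptor()].
#' @param D diffusion coefficient in cm^2/s (> 0).
#' @param medium free-text description of the medium.
#' @return a list with class \code{"ReferenceDiffusion"}.
#' @examples
#' referenceDiffusion()
#' @export
referenceDiffusion <- function(solute = soluteDescriptor("rhodamine B", 479),
                               D = 2.96e-6, medium = "1% agarose") {
  .assert(is.numeric(D) && D > 0, "reference D must be strictly positive")
  structure(list(solute = solute, D = D, medium = medium),
            class = "ReferenceDiffusion")
}

#' Estimate a diffusion coefficient by molecular-weight scaling
#'
#' Scales a measured tracer diffusivity to a target solute under the
#' Stokes-Einstein picture of a spherical solute whose radius grows with the
#' cube root of molecular weight:
#' \deqn{D_{target} = D_{ref} (Mw_{ref}/Mw_{target})^{1/3}.}
#' With the rhodamine B reference (479 g/mol, 2.96e-6 cm^2/s) this puts
#' CHIR99021 (465.34 g/mol) at about 2.99e-6 cm^2/s.
#'
#' @param target a [soluteDescriptor()] for the solute of interest.
#' @param reference a [referenceDiffusion()] measurement.
#' @return diffusion coefficient in cm^2/s.
#' @examples
#' estimateDiffusionCoefficient(soluteDescriptor("CHIR99021", 465.34))
#' @export
estimateDiffusionCoefficient <- function(target,
                                         reference = referenceDiffusion()) {
  .assert(inherits(target, "SoluteDescriptor"),
          "target must be a SoluteDescriptor")
  .assert(inherits(reference, "ReferenceDiffusion"),
          "reference must be a ReferenceDiffusion")
  mwRef <- reference$solute$molecularWeight
  .assert(mwRef > 0 && target$molecularWeight > 0,
          "molecular weights must be strictly positive")
  .assert(reference$D > 0, "reference D must be strictly positive")
  reference$D * (mwRef / target$molecularWeight)^(1 / 3)
}

# Exact solution of dC/dt = D d2C/dx2 on [0, L], C(0,t) = c1, C(L,t) = c2,
# C(x,0) = c1 in the interior. Two equivalent representations are used:
# the separation-of-variables sine series (fast for large Dt/L^2) and the
# telescoping image/erfc form (fast and accurate for small Dt/L^2, where
# the sine series needs very many terms). They agree to machine precision
# on their overlap.
.erfc <- function(z) 2 * pnorm(-z * sqrt(2))

.analyticProfile <- function(x, L, c1, c2, D, t, nterms = 200L) {
  if (t == 0) {
    conc <- rep(c1, length(x))
    conc[x >= L] <- c2
    return(conc)
  }
  tau <- D * t / L^2
  if (tau >= 0.04) {
    n <- seq_len(nterms)
    damp <- ((-1)^n / n) * exp(-n^2 * pi^2 * tau)
    s <- sin(outer(x / L, n * pi)) %*% damp   # length(x) vector
    c1 + (c2 - c1) * (x / L + (2 / pi) * as.numeric(s))
  } else {
    sig <- 2 * sqrt(D * t)
    K <- 0:(ceiling(12 * sqrt(tau)) + 2)
    acc <- rep(0, length(x))
    for (k in K) {
      acc <- acc + .erfc(((2 * k + 1) * L - x) / sig) -
        .erfc(((2 * k + 1) * L + x) / sig)
    }
    c1 + (c2 - c1) * acc
  }
}

#' Solve one-dimensional gradient formation in the channel
#'
#' Integrates 1D Fickian diffusion along the hydrogel channel with both
#' reservoirs held at fixed concentrations (daily medium renewal) and zero
#' initial CHIR in the interior. The analytic route evaluates the exact
#' series solution; the finite-difference route integrates the same problem
#' explicitly on the grid with automatic substepping keeping the stability
#' number D*dt/dx^2 at or below \code{maxStability}.
#'
#' @param geom a [channelGeometry()].
#' @param bc a [boundaryConditions()].
#' @param D diffusion coefficient in cm^2/s (> 0).
#' @param time time in seconds (>= 0); alternatively give \code{days}.
#' @param days time in days (used when \code{time} is missing).
#' @param method \code{"analytic_series"} or \code{"finite_difference"}.
#' @param nterms series truncation for the analytic route. At 200 terms the
#'   neglected tail is below exp(-200^2 pi^2 Dt/L^2)/200, i.e. far below
#'   1e-12 for any Dt/L^2 >= 4e-5; smaller times switch to an image-sum
#'   representation that is exact to machine precision there.
#' @param maxStability explicit-scheme stability bound (default 0.4).
#' @return a [ConcentrationProfile-class] on the axial grid.
#' @examples
#' prof <- solveProfile(days = 7, D = 1.25e-5)
#' head(as.data.frame(prof))
#' @export
solveProfile <- function(geom = channelGeometry(), bc = boundaryConditions(),
                         D, time = NULL, days = NULL,
                         method = c("analytic_series", "finite_difference"),
                         nterms = 200L, maxStability = 0.4) {
  method <- match.arg(method)
  if (is.null(time)) {
    .assert(!is.null(days), "give either time (s) or days")
    time <- days * .DAY
  }
  .assert(is.numeric(D) && D > 0, "D must be strictly positive")
  .assert(time >= 0, "time must be non-negative")
  L <- geom$length
  x <- seq(0, L, length.out = geom$nGrid)
  conc <- if (method == "analytic_series") {
    .analyticProfile(x, L, bc$cInlet1, bc$cInlet2, D, time, nterms)
  } else if (time == 0) {
    c0 <- rep(bc$cInlet1, geom$nGrid)
    c0[geom$nGrid] <- bc$cInlet2
    c0
  } else {
    # refine the grid internally while the diffusion front (width
    # ~ sqrt(Dt)) is under-resolved, then downsample: the step initial
    # condition at the source otherwise dominates the error at early times
    dx <- x[2] - x[1]
    f <- min(8L, max(1L, ceiling(dx / (sqrt(D * time) / 20))))
    nFine <- (geom$nGrid - 1L) * f + 1L
    c0 <- rep(bc$cInlet1, nFine)
    c0[nFine] <- bc$cInlet2
    fine <- .fd_diffuse_1d(c0, D, dx / f, time, maxStability)
    fine[seq(1L, nFine, by = f)]
  }
  ConcentrationProfile(x, conc, time = time, units = "uM")
}

# boxcar moving average with windows shrinking at the edges
.movingAverage <- function(y, halfwidth) {
  n <- length(y)
  if (halfwidth < 1) return(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - halfwidth, 1)
  hi <- pmin(seq_len(n) + halfwidth, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Tangent-based linearity score of a concentration profile
#'
#' Scores how close a profile is to a straight line by the ratio of the
#' tangent slope at the channel midpoint (50\% of the distance) to the
#' global end-to-end slope. The profile is first smoothed with a moving
#' average of width \code{smoothFrac} of the channel length; the midpoint
#' slope is then a central difference across \code{slopeFrac} of the length
#' on either side. An exactly linear profile scores 1; a diffusion front
#' that has not yet reached the far inlet scores well below 1.
#'
#' @param profile a [ConcentrationProfile-class] with at least 11 points.
#' @param smoothFrac moving-average window as a fraction of the channel
#'   length (default 0.05).
#' @param slopeFrac half-window of the midpoint central difference as a
#'   fraction of the channel length (default 0.05).
#' @param flatTol profiles whose end-to-end concentration difference is
#'   below this are rejected as flat (default 1e-9).
#' @return the dimensionless tangent ratio theta.
#' @examples
#' lin <- ConcentrationProfile(seq(0, 9, 0.1), seq(0, 9, 0.1))
#' linearityMetric(lin)  # exactly 1
#' @export
linearityMetric <- function(profile, smoothFrac = 0.05, slopeFrac = 0.05,
                            flatTol = 1e-9) {
  .assert(is(profile, "ConcentrationProfile"),
          "profile must be a ConcentrationProfile")
  x <- profile@positions
  y <- profile@concentrations
  n <- length(x)
  .assert(n >= 11, "linearity metric needs at least 11 points")
  span <- x[n] - x[1]
  dEnds <- y[n] - y[1]
  if (abs(dEnds) < flatTol)
    stop("linearity metric undefined for a flat profile", call. = FALSE)
  global <- dEnds / span
  dx <- mean(diff(x))
  smoothHw <- max(1L, round(smoothFrac * span / (2 * dx)))
  ys <- .movingAverage(y, smoothHw)
  mid <- which.min(abs(x - (x[1] + span / 2)))
  h <- max(1L, round(slopeFrac * span / dx))
  iLo <- max(1L, mid - h)
  iHi <- min(n, mid + h)
  local <- (ys[iHi] - ys[iLo]) / (x[iHi] - x[iLo])
  local / global
}

#' Earliest diffusion time giving a near-linear gradient
#'
#' Evaluates the tangent linearity score over candidate diffusion times and
#' returns the earliest one reaching \code{thetaMin}. Under fixed-reservoir
#' boundaries the score increases monotonically with time, so the returned
#' time is unique; if no candidate qualifies, the time scoring closest to 1
#' is returned and flagged.
#'
#' @param geom,bc,D as in [solveProfile()].
#' @param times candidate times in seconds, sorted increasing; alternatively
#'   give \code{days}.
#' @param days candidate times in days.
#' @param thetaMin linearity threshold defining "close to linear"
#'   (default 0.95).
#' @param ... passed to [solveProfile()] and [linearityMetric()].
#' @return a list with elements \code{tStar} (seconds), \code{theta}
#'   (scores per candidate time), \code{reached} (logical flag).
#' @examples
#' res <- optimalLinearTime(D = 1.25e-5, days = c(1, 3, 5, 7, 10, 15))
#' res$tStar / 86400
#' @export
optimalLinearTime <- function(geom = channelGeometry(),
                              bc = boundaryConditions(), D,
                              times = NULL, days = NULL, thetaMin = 0.95,
                              ...) {
  if (is.null(times)) {
    .assert(!is.null(days), "give either times (s) or days")
    times <- days * .DAY
  }
  .assert(length(times) >= 1, "times must be non-empty")
  .assert(!is.unsorted(times), "times must be sorted increasing")
  theta <- vapply(times, function(t) {
    linearityMetric(solveProfile(geom, bc, D, time = t), ...)
  }, numeric(1))
  ok <- which(theta >= thetaMin)
  if (length(ok)) {
    list(tStar = times[ok[1]], theta = theta, reached = TRUE)
  } else {
    list(tStar = times[which.min(abs(theta - 1))], theta = theta,
         reached = FALSE)
  }
}

#' Invert the linearity score for an effective diffusion coefficient
#'
#' Finds the diffusivity that makes the simulated gradient reach a given
#' linearity score at a given (observed) time, by bisection over a stated
#' bracket. Because the score is monotone increasing in D at fixed time,
#' the root is unique. This reconciles an empirically near-linear gradient
#' at a known time with the purely molecular diffusivity estimate, which on
#' its own predicts a much less linear profile.
#'
#' @param geom,bc as in [solveProfile()].
#' @param observedTime observed diffusion time in seconds; alternatively
#'   give \code{days}.
#' @param days observed time in days.
#' @param thetaTarget target linearity score, strictly inside (0, 1).
#' @param bracket search bracket for D in cm^2/s.
#' @param tol convergence tolerance on the achieved score (default 1e-3).
#' @param maxIter bisection iteration cap.
#' @return effective diffusion coefficient in cm^2/s.
#' @examples
#' invertEffectiveD(days = 7, thetaTarget = 0.95)
#' @export
invertEffectiveD <- function(geom = channelGeometry(),
                             bc = boundaryConditions(),
                             observedTime = NULL, days = NULL, thetaTarget,
                             bracket = c(1e-8, 1e-3), tol = 1e-3,
                             maxIter = 200L) {
  if (is.null(observedTime)) {
    .assert(!is.null(days), "give either observedTime (s) or days")
    observedTime <- days * .DAY
  }
  .assert(thetaTarget > 0 && thetaTarget < 1,
          "thetaTarget must be strictly inside (0, 1)")
  f <- function(D) {
    linearityMetric(solveProfile(geom, bc, D, time = observedTime)) -
      thetaTarget
  }
  fLo <- f(bracket[1]); fHi <- f(bracket[2])
  if (fLo > 0 || fHi < 0)
    stop(sprintf(
      paste0("thetaTarget %.4g not achievable in bracket [%g, %g]: ",
             "achievable range is [%.4g, %.4g]"),
      thetaTarget, bracket[1], bracket[2], fLo + thetaTarget,
      fHi + thetaTarget), call. = FALSE)
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    fm <- f(10^mid)
    if (abs(fm) <= tol) return(10^mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}
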