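# Independent oracles used across the suite. These are derived from closed
# forms or brute-force enumeration and never call the code paths they check.

# Closed-form tangent linearity of the fixed-reservoir diffusion profile:
# the exact midpoint-slope / global-slope ratio is
#   theta(tau) = 1 + 2 sum_m (-1)^m exp(-4 m^2 pi^2 tau),  tau = D t / L^2.
thetaClosed <- function(tau, M = 400) {
  m <- seq_len(M)
  1 + 2 * sum((-1)^m * exp(-4 * m^2 * pi^2 * tau))
}

# Analytic expectation of the *windowed* tangent estimator on the exact
# profile: boxcar smoothing over 2k+1 grid points attenuates mode n by the
# Dirichlet kernel mean(cos(n pi j dx / L)), and the central difference
# across +-h grid points turns the mode derivative into
# sin(n pi h dx / L) / (h dx). Only even modes survive at the midpoint.
thetaWindowedOracle <- function(tau, n = 901, L = 9, smoothFrac = 0.05,
                                slopeFrac = 0.05, M = 200) {
  dx <- L / (n - 1)
  k <- max(1, round(smoothFrac * L / (2 * dx)))
  h <- max(1, round(slopeFrac * L / dx))
  dirichlet <- function(nn) mean(cos(nn * pi * (-k:k) * dx / L))
  acc <- 1
  for (m in seq_len(M)) {
    acc <- acc + (-1)^m * (L / (m * pi * h * dx)) *
      exp(-4 * m^2 * pi^2 * tau) * dirichlet(2 * m) *
      sin(2 * m * pi * h * dx / L)
  }
  acc
}

# Coarse grid-search 4PL oracle: exhaustive over (log10 IC50, hill) with
# top/bottom profiled out by linear least squares at each grid point.
gridOracle4PL <- function(dose, viab, logGrid = seq(-2, 2, by = 0.01),
                          hillGrid = seq(0.5, 4, by = 0.05)) {
  n <- length(viab)
  mV <- mean(viab)
  syy <- sum((viab - mV)^2)
  ld <- log10(pmax(dose, .Machine$double.xmin))
  best <- list(rss = Inf)
  for (h in hillGrid) {
    w <- 1 / (1 + 10^(h * outer(ld, logGrid, "-")))
    w[dose == 0, ] <- 1
    mw <- colMeans(w)
    sww <- colSums(w^2) - n * mw^2
    swy <- colSums(w * viab) - n * mw * mV
    b <- swy / sww
    rss <- syy - b^2 * sww
    i <- which.min(rss)
    if (rss[i] < best$rss) {
      a <- mV - b[i] * mw[i]
      best <- list(rss = rss[i], logIC50 = logGrid[i], hill = h,
                   top = a + b[i], bottom = a)
    }
  }
  best
}

# Per-gene Welch test by direct t.test() calls.
bruteForceWelch <- function(mat, group) {
  treated <- mat[, group == "treated", drop = FALSE]
  control <- mat[, group == "control", drop = FALSE]
  res <- t(vapply(seq_len(nrow(mat)), function(i) {
    tt <- t.test(treated[i, ], control[i, ])
    c(p = tt$p.value, lfc = mean(treated[i, ]) - mean(control[i, ]))
  }, c(p = 0, lfc = 0)))
  data.frame(p = res[, "p"], lfc = res[, "lfc"])
}

# Mean of the piecewise-linear interpolant over [a, b] via a dense
# midpoint Riemann sum (independent of the package's trapezoid code).
quadMeanOracle <- function(x, y, a, b, nPts = 2e5) {
  f <- approxfun(x, y, rule = 2)
  h <- (b - a) / nPts
  mean(f(a + (seq_len(nPts) - 0.5) * h))
}

# ground-truth verdict set for the end-to-end screen
screenExpectations <- function() {
  c(tamoxifen = "non_zonal", isoniazid = "non_zonal",
    bromobenzene = "zonal", APAP = "zonal")
}

drugPresetNames <- function() {
  c(tamoxifen = "table1_tamoxifen", isoniazid = "table1_isoniazid",
    bromobenzene = "table1_bromobenzene", APAP = "table1_apap")
}
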