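test_that("molecular-weight scaling of the diffusion coefficient", {
  chir <- soluteDescriptor("CHIR99021", 465.34)
  # published estimate: 2.98e-6 cm^2/s from the rhodamine B reference
  expect_equal(estimateDiffusionCoefficient(chir), 2.98e-6,
               tolerance = 0.01)
  # identity: equal molecular weights leave D unchanged
  same <- soluteDescriptor("twin", 479)
  expect_identical(estimateDiffusionCoefficient(same), 2.96e-6)
  # exact cube: Mw ratio 8 doubles D
  ref <- referenceDiffusion(soluteDescriptor("big", 800), D = 1.0e-6)
  expect_equal(
    estimateDiffusionCoefficient(soluteDescriptor("small", 100), ref),
    2.0e-6, tolerance = 1e-12)
  # scale equivariance in the reference D
  ref2 <- referenceDiffusion(D = 3 * 2.96e-6)
  expect_equal(estimateDiffusionCoefficient(chir, ref2),
               3 * estimateDiffusionCoefficient(chir), tolerance = 1e-12)
  expect_error(soluteDescriptor("bad", -1), "positive")
  expect_error(referenceDiffusion(D = 0), "positive")
})

test_that("gradient solver honours initial, boundary and steady states", {
  geom <- channelGeometry()
  bc <- boundaryConditions()
  p0 <- solveProfile(geom, bc, D = 2.98e-6, time = 0)
  conc0 <- concentrations(p0)
  expect_equal(conc0[-length(conc0)], rep(0, length(conc0) - 1))
  expect_equal(conc0[length(conc0)], 9)
  # boundaries exact at all times, both methods
  for (m in c("analytic_series", "finite_difference")) {
    p <- solveProfile(geom, bc, D = 2.98e-6, days = 7, method = m)
    expect_identical(concentrations(p)[1], 0)
    expect_identical(concentrations(p)[geom$nGrid], 9)
  }
  # steady state: Dt/L^2 >= 2 is a straight line to 1e-6 uM
  tBig <- 2 * geom$length^2 / 2.98e-6
  pInf <- solveProfile(geom, bc, D = 2.98e-6, time = tBig)
  line <- 9 * positions(pInf) / geom$length
  expect_lt(max(abs(concentrations(pInf) - line)), 1e-6)
  # monotone in x whenever inlet2 > inlet1
  for (d in c(1, 4, 7, 12)) {
    p <- solveProfile(geom, bc, D = 2.98e-6, days = d)
    expect_true(all(diff(concentrations(p)) >= -1e-9))
    expect_gte(min(concentrations(p)), -1e-9)
    expect_lte(max(concentrations(p)), 9 * (1 + 1e-9))
  }
  expect_error(solveProfile(geom, bc, D = 2.98e-6, time = -1),
               "non-negative")
  expect_error(solveProfile(geom, bc, D = 0, time = 1), "positive")
})

test_that("analytic series and finite differences agree at day 7", {
  p1 <- solveProfile(D = 2.98e-6, days = 7)
  p2 <- solveProfile(D = 2.98e-6, days = 7, method = "finite_difference")
  expect_lt(max(abs(concentrations(p1) - concentrations(p2))), 1e-3)
})

test_that("tangent linearity metric matches its closed forms", {
  x <- seq(0, 9, length.out = 901)
  # definition: an exactly linear profile scores 1
  expect_equal(linearityMetric(ConcentrationProfile(x, x)), 1,
               tolerance = 1e-12)
  # limiting shapes: a mid-channel step has a huge tangent, a jump far
  # outside the mid-window leaves the midpoint flat (theta near 0)
  step <- ConcentrationProfile(x, ifelse(x < 4.5, 0, 9))
  expect_gt(linearityMetric(step), 5)
  edgeJump <- ConcentrationProfile(x, ifelse(x < 8.2, 0, 9))
  expect_lt(abs(linearityMetric(edgeJump)), 0.05)
  # solver profile at Dt/L^2 = 0.05: the windowed estimator equals its
  # analytic expectation (Dirichlet-attenuated series) to 1e-3 and the
  # ideal (window-free) closed form to the documented window bias
  D <- 2.98e-6; L <- 9
  tau <- 0.05
  prof <- solveProfile(D = D, time = tau * L^2 / D)
  th <- linearityMetric(prof)
  expect_equal(th, thetaWindowedOracle(tau), tolerance = 1e-3)
  expect_lt(abs(th - thetaClosed(tau)), 8e-3)
  # errors: flat profile, too few points
  expect_error(linearityMetric(ConcentrationProfile(x, rep(3, 901))),
               "flat")
  expect_error(
    linearityMetric(ConcentrationProfile(seq(0, 9, length.out = 5),
                                         seq(0, 9, length.out = 5))),
    "11 points")
})

test_that("theta grows monotonically in time towards 1", {
  D <- 1.25e-5
  days <- c(1, 2, 3, 5, 7, 10, 15)
  th <- vapply(days, function(d)
    linearityMetric(solveProfile(D = D, days = d)), numeric(1))
  expect_true(all(diff(th) > 0))
  expect_true(all(th > 0 & th < 1))
  thLate <- linearityMetric(solveProfile(D = D, time = 5 * 81 / D))
  expect_equal(thLate, 1, tolerance = 1e-3)
})

test_that("optimal linear time selection and diffusive time scaling", {
  D <- 1e-5
  # closed-form bisection oracle for theta = 0.95
  tauStar <- uniroot(function(tau) thetaClosed(tau) - 0.95,
                     c(0.01, 0.5), tol = 1e-12)$root
  tStar <- tauStar * 81 / D
  times <- seq(0.25, 15, by = 0.25) * 86400
  res <- optimalLinearTime(D = D, times = times, thetaMin = 0.95)
  expect_true(res$reached)
  # earliest grid time at/after the true crossing, within one grid step
  expect_lte(abs(res$tStar - times[which(times >= tStar)[1]]),
             diff(times)[1])
  # similarity: scaling D by 4 scales t* by 1/4 (on a 4x finer grid)
  res4 <- optimalLinearTime(D = 4 * D, times = times / 4,
                            thetaMin = 0.95)
  expect_equal(res4$tStar, res$tStar / 4, tolerance = 1e-9)
  # not-reached flag when no candidate qualifies
  early <- optimalLinearTime(D = D, times = times[1:4], thetaMin = 0.95)
  expect_false(early$reached)
  expect_equal(early$tStar, times[4])
})

test_that("effective-D inversion round-trips and orders correctly", {
  # round trip: theta achieved by a known D is inverted back within 1%
  D0 <- 5e-6
  th0 <- linearityMetric(solveProfile(D = D0, days = 7))
  expect_equal(invertEffectiveD(days = 7, thetaTarget = th0), D0,
               tolerance = 0.01)
  # day-7 near-linearity needs a much larger effective D than the
  # molecular-weight estimate; the value matches the closed-form oracle
  dEff <- invertEffectiveD(days = 7, thetaTarget = 0.95)
  expect_gt(dEff, 2.98e-6)
  tauStar <- uniroot(function(tau) thetaClosed(tau) - 0.95,
                     c(0.01, 0.5), tol = 1e-12)$root
  expect_equal(dEff, tauStar * 81 / (7 * 86400), tolerance = 0.02)
  # Dt invariance: doubling the observed time halves D_eff
  dHalf <- invertEffectiveD(days = 14, thetaTarget = 0.95)
  expect_equal(dHalf, dEff / 2, tolerance = 0.02)
  # unreachable target reports the achievable range
  expect_error(invertEffectiveD(days = 7, thetaTarget = 0.999,
                                bracket = c(1e-8, 1e-7)), "achievable")
  expect_error(invertEffectiveD(days = 7, thetaTarget = 1.2), "inside")
})
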