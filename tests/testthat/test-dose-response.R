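test_that("4PL fit recovers exact parameters from noise-free data", {
  d <- c(0, 200 / 2^(7:0))
  tbl <- data.frame(dose = d,
                    viability = fourPL(d, 100, 0, ic50 = 10, hill = 2))
  fit <- fit4PL(tbl)
  expect_true(isConverged(fit))
  expect_equal(ic50(fit), 10, tolerance = 1e-6)
  expect_equal(fit@top, 100, tolerance = 1e-6)
  expect_equal(fit@bottom, 0, tolerance = 1e-6)
  expect_equal(hillSlope(fit), 2, tolerance = 1e-6)
})

test_that("4PL fit agrees with an exhaustive grid-search oracle", {
  tbl <- genDoseResponse("table1_bromobenzene", "CHIR_9uM", seed = 21)
  fit <- fit4PL(tbl)
  oracle <- gridOracle4PL(tbl$dose, tbl$viability)
  expect_lte(abs(log10(ic50(fit)) - oracle$logIC50), 0.015)
  expect_lte(abs(hillSlope(fit) - oracle$hill), 0.05)
  # the continuous optimum cannot be worse than the best grid point
  expect_lte(fit@rss, oracle$rss + 1e-8)
})

test_that("tamoxifen preset lands inside the published interval", {
  tbl <- genDoseResponse("table1_tamoxifen", "untreated", seed = 1)
  fit <- fit4PL(tbl)
  expect_true(isConverged(fit))
  expect_gt(ic50(fit), 34.3)
  expect_lt(ic50(fit), 67.7)
  # fitted CI overlaps the printed 34.3-67.7 interval
  ci <- ic50CI(fit)
  expect_true(ci[1] < 67.7 && ci[2] > 34.3)
})

test_that("4PL fit is equivariant under dose-unit rescaling", {
  tbl <- genDoseResponse("table1_apap", "CHIR_9uM", seed = 5)
  fit1 <- fit4PL(tbl)
  tbl2 <- transform(tbl, dose = dose * 1000)   # mM -> uM
  fit2 <- fit4PL(tbl2)
  expect_equal(ic50(fit2), 1000 * ic50(fit1), tolerance = 1e-6)
  expect_equal(hillSlope(fit2), hillSlope(fit1), tolerance = 1e-6)
  expect_equal(fit2@top, fit1@top, tolerance = 1e-6)
  expect_equal(fit2@bottom, fit1@bottom, tolerance = 1e-6)
  expect_equal(fit2@logIC50SE, fit1@logIC50SE, tolerance = 1e-4)
})

test_that("4PL fit rejects under-determined tables", {
  expect_error(fit4PL(data.frame(dose = c(0, 1, 2, 4),
                                 viability = c(100, 90, 60, 20))),
               "4 distinct")
  expect_error(fit4PL(data.frame(dose = c(1, 2, 4, 8),
                                 viability = c(1, 2, Inf, 3))), "finite")
})

test_that("IC50 comparison flags the published shifts and only those", {
  fits <- lapply(c(untreated = "untreated", chir9 = "CHIR_9uM"),
                 function(cond) {
    lapply(drugPresetNames(), function(p)
      fit4PL(genDoseResponse(p, cond, seed = 11)))
  })
  # identical fits: ratio 1, p = 1
  same <- compareIC50(fits$untreated$tamoxifen, fits$untreated$tamoxifen)
  expect_equal(same$ratio, 1)
  expect_equal(same$p, 1)
  expect_false(same$significant)
  # bromobenzene and APAP shift significantly under 9 uM CHIR
  expect_true(compareIC50(fits$untreated$bromobenzene,
                          fits$chir9$bromobenzene)$significant)
  expect_true(compareIC50(fits$untreated$APAP,
                          fits$chir9$APAP)$significant)
  # isoniazid (13.3 vs 13.2) does not
  expect_false(compareIC50(fits$untreated$isoniazid,
                           fits$chir9$isoniazid)$significant)
  # unconverged input is refused
  bad <- fits$untreated$tamoxifen
  bad@converged <- FALSE
  expect_error(compareIC50(bad, fits$chir9$tamoxifen), "converged")
})

test_that("IC50 shift test keeps its size under the null", {
  # both conditions drawn from the same ground truth (isoniazid untreated)
  nSim <- 500
  rejections <- vapply(seq_len(nSim), function(i) {
    fa <- fit4PL(genDoseResponse("table1_isoniazid", "untreated",
                                 seed = 20000 + 2 * i))
    fb <- fit4PL(genDoseResponse("table1_isoniazid", "untreated",
                                 seed = 20001 + 2 * i))
    compareIC50(fa, fb)$significant
  }, logical(1))
  expect_lte(mean(rejections), 0.07)
})

test_that("fold-induction calibration behaves per its anchors", {
  for (cyp in c("CYP1A2", "CYP2E1", "CYP3A4", "CYP2B6"))
    expect_equal(inductionAt(inductionCurve(cyp), 0), 1)
  expect_equal(inductionAt(inductionCurve("CYP1A2"), 9), 20)
  expect_equal(inductionAt(inductionCurve("CYP2E1"), 9), 5)
  expect_equal(inductionAt(inductionCurve("CYP2B6"), 9), 1)
  # log-linear midpoint: geometric mean of flanking points
  cv <- inductionCurve("CYP1A2", chir = c(3, 6), fold = c(2, 8))
  expect_equal(inductionAt(cv, 4.5), sqrt(2 * 8))
  # clamped beyond the calibrated range
  expect_equal(inductionAt(cv, 15), 20)
  # monotone interpolation between monotone points
  chirGrid <- seq(0, 9, by = 0.25)
  expect_true(all(diff(inductionAt(cv, chirGrid)) >= 0))
  expect_error(inductionAt(cv, -1), "non-negative")
})

test_that("CYP activity normalization is a guarded ratio", {
  expect_equal(normalizeCypActivity(1000, 1.0), 1000)
  expect_equal(normalizeCypActivity(1000, 2.0),
               normalizeCypActivity(1000, 1.0) / 2)
  expect_equal(normalizeCypActivity(2400, 1.2, control = c(800, 0.8)), 2.0)
  expect_error(normalizeCypActivity(1000, 0), "positive")
})
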