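linProfile <- function() {
  x <- seq(0, 9, by = 0.01)
  ConcentrationProfile(x, x)
}

test_that("channel sectioning averages CHIR per equal-width slice", {
  s3 <- sectionChannel(linProfile(), 3)
  expect_equal(s3$mean_chir, c(1.5, 4.5, 7.5), tolerance = 1e-9)
  expect_identical(s3$label,
                   c("zone1_like", "zone2_like", "zone3_like"))
  # uniform profile: all means equal
  x <- seq(0, 9, by = 0.01)
  sU <- sectionChannel(ConcentrationProfile(x, rep(4, length(x))), 6)
  expect_equal(sU$mean_chir, rep(4, 6))
  # section n is nearest Inlet 2 (the CHIR source)
  expect_equal(sU$x_hi[6], 9)
  expect_equal(sU$x_lo[1], 0)
  # day-7 solver profile vs independent quadrature oracle
  prof <- solveProfile(D = 1.2514e-5, days = 7)
  s6 <- sectionChannel(prof, 6)
  oracle <- vapply(seq_len(6), function(i)
    quadMeanOracle(positions(prof), concentrations(prof),
                   s6$x_lo[i], s6$x_hi[i]), numeric(1))
  expect_equal(s6$mean_chir, oracle, tolerance = 1e-6)
  expect_error(sectionChannel(linProfile(), 4), "3 or 6")
  expect_warning(sectionChannel(linProfile(), 4, override = TRUE),
                 "non-standard")
})

test_that("local IC50 interpolates the anchors on the log scale", {
  bb <- getPreset("table1_bromobenzene")
  expect_equal(localIC50(bb, 0), 12.5)
  expect_equal(localIC50(bb, 9), 0.8)
  expect_equal(localIC50(bb, 4.5), sqrt(12.5 * 0.8), tolerance = 1e-12)
  # clamped outside the calibrated range
  expect_equal(localIC50(bb, 12), 0.8)
  # isoniazid is near-constant across the channel
  iso <- localIC50(getPreset("table1_isoniazid"), seq(0, 9, 0.5))
  expect_lt(max(iso) / min(iso), 1.01)
  expect_error(localIC50(bb, -1), "non-negative")
})

test_that("predicted viability surfaces honour the model structure", {
  prof <- solveProfile(D = 1.2514e-5, days = 7)
  s6 <- sectionChannel(prof, 6)
  apap <- getPreset("table1_apap")
  doses <- c(0, 20 / 2^(7:0))
  surf <- predictViabilitySurface(apap, s6, doses)
  v <- viability(surf)
  # dose 0 column is the top asymptote in every section
  expect_equal(v[, 1], rep(apap@top, 6))
  # monotone non-increasing in dose for every section
  expect_true(all(apply(v, 1, function(r) all(diff(r) <= 1e-9))))
  # at 10 mM APAP the high-CHIR end is hit harder
  v10 <- predictViabilitySurface(apap, s6, 10)
  expect_lt(viability(v10)[6, 1], viability(v10)[1, 1])
  # tamoxifen's zonal contrast never exceeds APAP's at half-max dose
  tam <- getPreset("table1_tamoxifen")
  tamSurf <- viability(predictViabilitySurface(
    tam, s6, c(0, 100 / 2^(7:0))))
  tamContrast <- max(apply(tamSurf, 2, function(col) diff(range(col))))
  apapHalf <- viability(predictViabilitySurface(apap, s6, 10))
  expect_lte(tamContrast, diff(range(apapHalf)))
})

test_that("zonality verdicts from the published anchors", {
  # identical anchors: index 0, non-zonal
  flat <- list(drug = "flat", ic50 = c(untreated = 5, chir9 = 5),
               logIC50SE = c(untreated = 0.02, chir9 = 0.02))
  z0 <- zonalityIndex(flat)
  expect_equal(z0$zonality_index, 0)
  expect_identical(z0$verdict, "non_zonal")
  # bromobenzene: index log10(12.5/0.8) = 1.194, zonal
  zb <- zonalityIndex(getPreset("table1_bromobenzene"))
  expect_equal(zb$zonality_index, log10(12.5 / 0.8), tolerance = 1e-12)
  expect_identical(zb$verdict, "zonal")
  # tamoxifen: 1.45x with overlapping CIs -> non-zonal
  expect_identical(zonalityIndex(getPreset("table1_tamoxifen"))$verdict,
                   "non_zonal")
  expect_identical(zonalityIndex(getPreset("table1_isoniazid"))$verdict,
                   "non_zonal")
  expect_identical(zonalityIndex(getPreset("table1_apap"))$verdict,
                   "zonal")
  # missing SEs: verdict withheld
  noSE <- list(drug = "x", ic50 = c(untreated = 10, chir9 = 2),
               logIC50SE = c(untreated = NA_real_, chir9 = NA_real_))
  expect_identical(zonalityIndex(noSE)$verdict, "withheld")
  # dose-unit invariance of the index
  scaled <- list(drug = "x", ic50 = 1000 * c(untreated = 10, chir9 = 2),
                 logIC50SE = c(untreated = 0.02, chir9 = 0.02))
  unscaled <- list(drug = "x", ic50 = c(untreated = 10, chir9 = 2),
                   logIC50SE = c(untreated = 0.02, chir9 = 0.02))
  expect_equal(zonalityIndex(scaled)$zonality_index,
               zonalityIndex(unscaled)$zonality_index)
})

test_that("a single synthetic screen refit recovers each drug's verdict", {
  expect_verdicts <- screenExpectations()
  for (d in names(drugPresetNames())) {
    scr <- genZonalScreen(drugPresetNames()[[d]], seed = 42)
    zf <- fitZonalScreen(scr$screen, scr$sections, drug = d)
    expect_true(zf$converged)
    # fitted section IC50s track the generator's ground truth
    est <- vapply(zf$fits, ic50, numeric(1))
    expect_equal(unname(log10(est)), log10(scr$truthIC50),
                 tolerance = 0.15)
    expect_identical(zonalityIndex(zf)$verdict, expect_verdicts[[d]])
  }
  # positive index means the zone-3-like end is the more sensitive one
  scr <- genZonalScreen("table1_apap", seed = 42)
  zf <- fitZonalScreen(scr$screen, scr$sections, drug = "APAP")
  expect_gt(zonalityIndex(zf)$zonality_index, 0)
})
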