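# --- ground-truth registry -------------------------------------------------
#
# IC50 anchors and printed 95% CIs are the published plate-assay values
# (untreated vs 9 uM CHIR pretreatment); log10-scale SEs are back-calculated
# from the printed CIs assuming a symmetric interval on the linear scale
# (half-width / 1.96, delta method). The shared 4PL shape (top 100, bottom
# 0, hill 2) is not published and is a documented modelling choice: a full
# viability span and a typical CCK-8 cytotoxicity steepness.
#
# The gradient default is the *effective* channel diffusivity: the
# molecular-weight-scaled estimate (2.99e-6 cm^2/s) does not produce a
# near-linear 9 cm gradient in 7 days on its own, so the generators use the
# diffusivity at which the day-7 tangent linearity reaches 0.95, obtained
# from invertEffectiveD (1.2514e-5 cm^2/s; verified by a round-trip test).

.NOISE_DEFAULTS <- list(viability_sd = 5, ct_sd = 0.2,
                        image_noise_frac = 0.02)
.GRADIENT_DEFAULTS <- list(D = 1.2514e-5, time = 7 * 86400)
.SHAPE_DEFAULTS <- list(top = 100, bottom = 0, hill = 2)

.seFromCI <- function(ic50, lo, hi) {
  ((hi - lo) / 2 / 1.96) / (ic50 * log(10))
}

.makeDrugPreset <- function(name, drug, unit, ic50U, ciU, ic50C, ciC,
                            plateTop, channelTop) {
  ci <- rbind(untreated = ciU, chir9 = ciC)
  colnames(ci) <- c("lo", "hi")
  new("SyntheticPreset",
      name = name, drug = drug, doseUnit = unit,
      top = .SHAPE_DEFAULTS$top, bottom = .SHAPE_DEFAULTS$bottom,
      hill = .SHAPE_DEFAULTS$hill,
      ic50 = c(untreated = ic50U, chir9 = ic50C),
      ic50CI95 = ci,
      logIC50SE = c(untreated = .seFromCI(ic50U, ciU[1], ciU[2]),
                    chir9 = .seFromCI(ic50C, ciC[1], ciC[2])),
      plateTopDose = plateTop, channelTopDose = channelTop,
      noise = .NOISE_DEFAULTS, gradient = .GRADIENT_DEFAULTS)
}

.drugPresets <- function() {
  list(
    table1_tamoxifen = .makeDrugPreset(
      "table1_tamoxifen", "tamoxifen", "uM",
      51.0, c(34.3, 67.7), 35.2, c(25.5, 44.8), 200, 100),
    table1_isoniazid = .makeDrugPreset(
      "table1_isoniazid", "isoniazid", "uM",
      13.3, c(12.5, 14.1), 13.2, c(12.1, 14.3), 200, 200),
    table1_bromobenzene = .makeDrugPreset(
      "table1_bromobenzene", "bromobenzene", "uM",
      12.5, c(9.3, 15.7), 0.8, c(0.4, 1.2), 50, 500),
    table1_apap = .makeDrugPreset(
      "table1_apap", "APAP", "mM",
      10.0, c(9.7, 10.3), 4.2, c(3.2, 5.2), 20, 200)
  )
}

.qpcrPresets <- function() {
  list(
    cyp1a2_chir9 = list(cyp = "CYP1A2", chir = 9),
    cyp2e1_chir9 = list(cyp = "CYP2E1", chir = 9),
    cyp3a4_chir9 = list(cyp = "CYP3A4", chir = 9),
    cyp2b6_chir9 = list(cyp = "CYP2B6", chir = 9)
  )
}

#' List the names of all registered synthetic presets
#'
#' @return character vector of preset names: four drug presets anchored to
#'   the published IC50 table and four qPCR induction presets anchored to
#'   the published fold inductions at 9 uM CHIR.
#' @examples
#' listPresets()
#' @export
listPresets <- function() {
  c(names(.drugPresets()), names(.qpcrPresets()))
}

#' Retrieve a synthetic ground-truth preset by name
#'
#' Drug presets (\code{table1_*}) return a [SyntheticPreset-class]; qPCR
#' presets (\code{cyp*_chir9}) return a list with elements \code{cyp} and
#' \code{chir}.
#'
#' @param name a name from [listPresets()].
#' @return the preset object.
#' @examples
#' getPreset("table1_apap")
#' @export
getPreset <- function(name) {
  dp <- .drugPresets(); qp <- .qpcrPresets()
  if (name %in% names(dp)) return(dp[[name]])
  if (name %in% names(qp)) return(structure(qp[[name]],
                                            class = "QpcrPreset"))
  stop(sprintf("unknown preset '%s'; see listPresets()", name),
       call. = FALSE)
}
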