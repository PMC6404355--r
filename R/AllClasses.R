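#' @import methods
#' @importFrom stats approx coef integrate median nls optim optimHess
#'   pnorm pt qt quantile rnorm runif sd setNames uniroot var vcov
#' @importFrom utils head read.csv tail write.csv
NULL

#' ConcentrationProfile: morphogen concentration along the channel axis
#'
#' Holds a one-dimensional concentration (or relative-intensity) profile at a
#' single time point: the object exchanged between the gradient solver, the
#' image profiler and the channel sectioner.
#'
#' @slot positions numeric, axial positions in cm, strictly increasing,
#'   spanning the channel.
#' @slot concentrations numeric, same length as \code{positions}; in uM for
#'   solver output, or dimensionless relative units in [0, 1] when derived
#'   from a normalized image.
#' @slot time numeric(1), time in seconds since the reservoirs were attached.
#' @slot units character(1), \code{"uM"} or \code{"relative"}.
#'
#' @seealso [solveProfile()], [extractAxialProfile()], [sectionChannel()]
#' @export
setClass("ConcentrationProfile",
  representation(
    positions = "numeric",
    concentrations = "numeric",
    time = "numeric",
    units = "character"
  ),
  prototype(time = 0, units = "uM")
)

setValidity("ConcentrationProfile", function(object) {
  msg <- NULL
  if (length(object@positions) != length(object@concentrations))
    msg <- c(msg, "positions and concentrations must have the same length")
  if (length(object@positions) >= 2 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@time) != 1 || !is.finite(object@time) || object@time < 0)
    msg <- c(msg, "time must be a single non-negative number")
  if (!object@units %in% c("uM", "relative"))
    msg <- c(msg, "units must be 'uM' or 'relative'")
  if (anyNA(object@concentrations))
    msg <- c(msg, "concentrations must not contain NA")
  if (is.null(msg)) TRUE else msg
})

#' FourPLFit: fitted four-parameter-logistic dose-response curve
#'
#' The result of [fit4PL()]: a viability-vs-dose curve
#' \deqn{V(d) = bottom + (top - bottom) / (1 + (d/IC_{50})^{hill})}
#' fitted by least squares in log10(IC50), with an asymptotic 95\% confidence
#' interval for the IC50.
#'
#' @slot top numeric(1), upper asymptote (\% viability).
#' @slot bottom numeric(1), lower asymptote (\% viability).
#' @slot hill numeric(1), Hill slope (> 0; viability falls with dose).
#' @slot ic50 numeric(1), half-maximal inhibitory concentration (dose units).
#' @slot ic50CI numeric(2), 95\% confidence interval for the IC50.
#' @slot logIC50SE numeric(1), standard error of log10(IC50).
#' @slot rss numeric(1), residual sum of squares.
#' @slot df numeric(1), residual degrees of freedom.
#' @slot converged logical(1).
#' @slot message character(1), fitting diagnostics when not converged.
#'
#' @seealso [fit4PL()], [compareIC50()]
#' @export
setClass("FourPLFit",
  representation(
    top = "numeric", bottom = "numeric", hill = "numeric",
    ic50 = "numeric", ic50CI = "numeric", logIC50SE = "numeric",
    rss = "numeric", df = "numeric", converged = "logical",
    message = "character"
  ),
  prototype(message = "")
)

setValidity("FourPLFit", function(object) {
  msg <- NULL
  if (length(object@ic50CI) != 2)
    msg <- c(msg, "ic50CI must have length 2")
  if (isTRUE(object@converged)) {
    if (object@bottom >= object@top)
      msg <- c(msg, "bottom must be below top")
    if (object@ic50 <= 0)
      msg <- c(msg, "ic50 must be positive")
    if (object@hill <= 0)
      msg <- c(msg, "hill must be positive")
    if (object@ic50CI[1] > object@ic50 || object@ic50CI[2] < object@ic50)
      msg <- c(msg, "ic50 must lie inside its confidence interval")
  }
  if (is.null(msg)) TRUE else msg
})

#' ChannelImage: one dye channel of a ChemiDoc-style channel scan
#'
#' A 2D intensity raster of the hydrogel channel for a single dye, with a
#' boolean mask of in-channel pixels. Columns run along the channel axis with
#' the origin at Inlet 1 (the DMSO-only reservoir); Inlet 2 (the CHIR source)
#' is at the right edge.
#'
#' @slot pixels numeric matrix of non-negative intensities (a.u.).
#' @slot dye character(1): \code{"chir_uv"} (CHIR UV absorbance),
#'   \code{"celltracker"} (CellTracker Deep Red, cell distribution) or
#'   \code{"ethd1"} (EthD-1, membrane-damaged cells).
#' @slot pixelSize numeric(1), cm per pixel.
#' @slot mask logical matrix, same shape as \code{pixels}; TRUE inside the
#'   channel.
#'
#' @seealso [extractAxialProfile()], [damageFractionBySection()]
#' @export
setClass("ChannelImage",
  representation(
    pixels = "matrix", dye = "character",
    pixelSize = "numeric", mask = "matrix"
  )
)

setValidity("ChannelImage", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixels))
    msg <- c(msg, "pixels must be numeric")
  if (any(object@pixels < 0, na.rm = TRUE))
    msg <- c(msg, "pixel intensities must be non-negative")
  if (!object@dye %in% c("chir_uv", "celltracker", "ethd1"))
    msg <- c(msg, "dye must be one of 'chir_uv', 'celltracker', 'ethd1'")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (!is.logical(object@mask) ||
      !identical(dim(object@mask), dim(object@pixels)))
    msg <- c(msg, "mask must be a logical matrix with the shape of pixels")
  if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one in-channel pixel")
  if (is.null(msg)) TRUE else msg
})

#' ZonalViabilitySurface: viability over (channel section x drug dose)
#'
#' The screening-surface object: percent viability for each channel section
#' at each drug dose, either predicted from a fitted model or observed in a
#' (synthetic) screen. Section n is the section nearest Inlet 2, i.e. the
#' zone-3-like high-CHIR end.
#'
#' @slot drug character(1).
#' @slot sections data.frame as returned by [sectionChannel()].
#' @slot doses numeric, drug doses (declared unit), non-negative.
#' @slot doseUnit character(1), e.g. \code{"uM"} or \code{"mM"}.
#' @slot viability numeric matrix, sections x doses, percent of untreated.
#' @slot provenance character(1), \code{"predicted"} or \code{"observed"}.
#'
#' @seealso [predictViabilitySurface()]
#' @export
setClass("ZonalViabilitySurface",
  representation(
    drug = "character", sections = "data.frame", doses = "numeric",
    doseUnit = "character", viability = "matrix", provenance = "character"
  )
)

setValidity("ZonalViabilitySurface", function(object) {
  msg <- NULL
  if (nrow(object@viability) != nrow(object@sections))
    msg <- c(msg, "viability must have one row per section")
  if (ncol(object@viability) != length(object@doses))
    msg <- c(msg, "viability must have one column per dose")
  if (any(object@doses < 0))
    msg <- c(msg, "doses must be non-negative")
  if (!object@provenance %in% c("predicted", "observed"))
    msg <- c(msg, "provenance must be 'predicted' or 'observed'")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticPreset: named ground-truth parameter set for the generators
#'
#' Bundles the calibrated ground truth that the synthetic-data generators
#' emulate and the fitters are expected to recover: per-condition 4PL
#' parameters anchored to the published IC50 table, CYP fold-induction
#' calibration, gradient parameters, the damage-vs-CHIR readout rule and the
#' noise model. Identical (preset, seed) pairs give bit-identical outputs.
#'
#' @slot name character(1), registry name (e.g. \code{"table1_bromobenzene"}).
#' @slot drug character(1).
#' @slot doseUnit character(1).
#' @slot top,bottom,hill numeric(1), shared 4PL shape parameters.
#' @slot ic50 named numeric: \code{untreated} and \code{chir9} anchors.
#' @slot ic50CI95 numeric matrix 2x2 (rows: untreated, chir9) of printed
#'   95\% confidence bounds.
#' @slot logIC50SE named numeric, log10-scale SEs back-calculated from the
#'   printed confidence intervals.
#' @slot plateTopDose numeric(1), top dose of the plate assay dilution series.
#' @slot channelTopDose numeric(1), top dose of the channel screen series.
#' @slot noise list: \code{viability_sd} (\% points), \code{ct_sd} (cycles),
#'   \code{image_noise_frac} (fraction of image dynamic range).
#' @slot gradient list: \code{D} (cm^2/s), \code{time} (s) of the gradient
#'   used by the channel generators.
#'
#' @seealso [getPreset()], [listPresets()], [genDoseResponse()]
#' @export
setClass("SyntheticPreset",
  representation(
    name = "character", drug = "character", doseUnit = "character",
    top = "numeric", bottom = "numeric", hill = "numeric",
    ic50 = "numeric", ic50CI95 = "matrix", logIC50SE = "numeric",
    plateTopDose = "numeric", channelTopDose = "numeric",
    noise = "list", gradient = "list"
  )
)

setValidity("SyntheticPreset", function(object) {
  msg <- NULL
  if (!all(c("untreated", "chir9") %in% names(object@ic50)))
    msg <- c(msg, "ic50 must carry 'untreated' and 'chir9' anchors")
  if (any(object@ic50 <= 0))
    msg <- c(msg, "IC50 anchors must be positive")
  if (object@bottom >= object@top)
    msg <- c(msg, "bottom must be below top")
  if (object@hill <= 0)
    msg <- c(msg, "hill must be positive")
  if (is.null(msg)) TRUE else msg
})

#' InductionCurve: CHIR concentration to CYP mRNA fold induction
#'
#' A piecewise log-linear calibration of fold induction of one CYP mRNA as a
#' function of CHIR concentration, anchored at (0 uM, 1-fold). Interpolation
#' is linear in log(fold) vs CHIR and clamps at the last calibrated point.
#'
#' @slot cyp character(1): one of CYP1A2, CYP2E1, CYP3A4, CYP2B6.
#' @slot chir numeric, calibration CHIR concentrations (uM), sorted, starts
#'   at 0.
#' @slot fold numeric, fold induction at each calibration point; fold[1] = 1.
#'
#' @seealso [inductionCurve()], [inductionAt()]
#' @export
setClass("InductionCurve",
  representation(cyp = "character", chir = "numeric", fold = "numeric")
)

setValidity("InductionCurve", function(object) {
  msg <- NULL
  if (length(object@chir) != length(object@fold))
    msg <- c(msg, "chir and fold must have the same length")
  if (length(object@chir) < 2)
    msg <- c(msg, "need at least two calibration points")
  if (object@chir[1] != 0 || object@fold[1] != 1)
    msg <- c(msg, "curve must be anchored at (0 uM, 1-fold)")
  if (any(diff(object@chir) <= 0))
    msg <- c(msg, "chir points must be strictly increasing")
  if (any(object@fold < 0))
    msg <- c(msg, "fold inductions must be non-negative")
  if (is.null(msg)) TRUE else msg
})
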