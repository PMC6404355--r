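#' @rdname accessors
#' @export
setMethod("positions", "ConcentrationProfile",
          function(object) object@positions)

#' @rdname accessors
#' @export
setMethod("concentrations", "ConcentrationProfile",
          function(object) object@concentrations)

#' @rdname accessors
#' @export
setMethod("profileTime", "ConcentrationProfile",
          function(object) object@time)

#' @rdname accessors
#' @export
setMethod("ic50", "FourPLFit", function(object) object@ic50)

#' @rdname accessors
#' @export
setMethod("ic50CI", "FourPLFit", function(object) object@ic50CI)

#' @rdname accessors
#' @export
setMethod("hillSlope", "FourPLFit", function(object) object@hill)

#' @rdname accessors
#' @export
setMethod("isConverged", "FourPLFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("viability", "ZonalViabilitySurface",
          function(object) object@viability)

#' @rdname accessors
#' @export
setMethod("sections", "ZonalViabilitySurface",
          function(object) object@sections)

#' @rdname accessors
#' @export
setMethod("channelMask", "ChannelImage", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ChannelImage", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setMethod("dyeName", "ChannelImage", function(object) object@dye)

#' Coerce a ConcentrationProfile to a data.frame
#'
#' @param x a [ConcentrationProfile-class].
#' @param ... ignored.
#' @return data.frame with columns \code{position_cm},
#'   \code{concentration_uM}, \code{time_days}.
#' @export
as.data.frame.ConcentrationProfile <- function(x, ...) {
  data.frame(
    position_cm = x@positions,
    concentration_uM = x@concentrations,
    time_days = x@time / 86400
  )
}

setMethod("show", "ConcentrationProfile", function(object) {
  cat(sprintf(
    "ConcentrationProfile: %d points over [%.3g, %.3g] cm at t = %.3g d (%s)\n",
    length(object@positions), min(object@positions), max(object@positions),
    object@time / 86400, object@units))
  cat(sprintf("  concentration range: [%.4g, %.4g]\n",
              min(object@concentrations), max(object@concentrations)))
})

setMethod("show", "FourPLFit", function(object) {
  cat("FourPLFit\n")
  cat(sprintf("  IC50: %.4g  (95%% CI %.4g - %.4g)\n",
              object@ic50, object@ic50CI[1], object@ic50CI[2]))
  cat(sprintf("  top: %.3g  bottom: %.3g  hill: %.3g\n",
              object@top, object@bottom, object@hill))
  cat(sprintf("  rss: %.4g on %g df; converged: %s\n",
              object@rss, object@df, object@converged))
  if (nzchar(object@message)) cat("  note:", object@message, "\n")
})

setMethod("show", "ChannelImage", function(object) {
  cat(sprintf("ChannelImage [%s]: %d x %d px, %.4g cm/px, %d masked px\n",
              object@dye, nrow(object@pixels), ncol(object@pixels),
              object@pixelSize, sum(object@mask)))
})

setMethod("show", "ZonalViabilitySurface", function(object) {
  cat(sprintf("ZonalViabilitySurface (%s, %s): %d sections x %d doses [%s]\n",
              object@drug, object@provenance, nrow(object@viability),
              length(object@doses), object@doseUnit))
})

setMethod("show", "SyntheticPreset", function(object) {
  cat(sprintf("SyntheticPreset '%s' (%s, doses in %s)\n",
              object@name, object@drug, object@doseUnit))
  cat(sprintf("  IC50 untreated: %.4g   9 uM CHIR: %.4g\n",
              object@ic50[["untreated"]], object@ic50[["chir9"]]))
  cat(sprintf("  shape: top %.3g / bottom %.3g / hill %.3g\n",
              object@top, object@bottom, object@hill))
})

setMethod("show", "InductionCurve", function(object) {
  cat(sprintf("InductionCurve %s: ", object@cyp))
  cat(paste(sprintf("(%g uM, %.3g x)", object@chir, object@fold),
            collapse = " "), "\n")
})
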