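#' Construct a ChannelImage
#'
#' @param pixels numeric matrix of non-negative intensities; columns run
#'   along the channel axis, origin (column 1) at Inlet 1.
#' @param dye \code{"chir_uv"}, \code{"celltracker"} or \code{"ethd1"}.
#' @param pixelSize cm per pixel (default 0.01).
#' @param mask logical matrix of in-channel pixels; default all TRUE.
#' @return a [ChannelImage-class].
#' @export
channelImage <- function(pixels, dye, pixelSize = 0.01, mask = NULL) {
  pixels <- as.matrix(pixels)
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  new("ChannelImage", pixels = pixels, dye = dye,
      pixelSize = pixelSize, mask = mask)
}

#' Estimate image background
#'
#' Background is the median intensity of the pixels outside the channel
#' mask — the ChemiDoc bed around the hydrogel. With an all-TRUE mask
#' (no outside pixels) the minimum in-channel intensity is used.
#'
#' @param img a [ChannelImage-class].
#' @return background intensity (a.u.).
#' @export
estimateBackground <- function(img) {
  .assert(is(img, "ChannelImage"), "img must be a ChannelImage")
  outside <- img@pixels[!img@mask]
  if (length(outside)) median(outside) else min(img@pixels[img@mask])
}

#' Extract the axial intensity profile of a channel image
#'
#' Averages masked pixel intensities in each image column, yielding mean
#' intensity versus axial position (column index times pixel size, origin
#' at Inlet 1). Columns whose mask is empty are dropped and reported via an
#' attribute.
#'
#' @param img a [ChannelImage-class].
#' @return a [ConcentrationProfile-class] in relative units (unnormalized
#'   intensity, a.u.), with attribute \code{"dropped"} listing any dropped
#'   column indices.
#' @examples
#' img <- channelImage(matrix(1:20, 4, 5), "chir_uv")
#' concentrations(extractAxialProfile(img))
#' @export
extractAxialProfile <- function(img) {
  .assert(is(img, "ChannelImage"), "img must be a ChannelImage")
  counts <- colSums(img@mask)
  .assert(any(counts > 0), "mask is empty")
  keep <- counts > 0
  sums <- colSums(img@pixels * img@mask)
  meanI <- sums[keep] / counts[keep]
  # axial origin at Inlet 1: the first in-channel column, not the image
  # frame edge (the scan includes a background margin around the channel)
  xs <- (which(keep) - min(which(keep)) + 0.5) * img@pixelSize
  prof <- ConcentrationProfile(xs, meanI, time = 0, units = "relative")
  attr(prof, "dropped") <- which(!keep)
  prof
}

#' Normalize an intensity profile to its saturated maximum
#'
#' Converts raw axial intensity to relative concentration:
#' (I - background) / (I_sat - background), clipped to [0, 1], where the
#' saturation anchor I_sat is the 99.5th-percentile intensity over the 5\%
#' of the channel adjacent to Inlet 2 (the source end, where the signal has
#' reached its reservoir plateau).
#'
#' @param profile a [ConcentrationProfile-class] of raw intensities.
#' @param background background intensity (a.u.), e.g. from
#'   [estimateBackground()].
#' @param tailFrac fraction of the channel next to Inlet 2 used for the
#'   saturation anchor (default 0.05).
#' @param prob quantile used within the tail (default 0.995).
#' @return a normalized [ConcentrationProfile-class] in [0, 1].
#' @export
normalizeToSaturation <- function(profile, background, tailFrac = 0.05,
                                  prob = 0.995) {
  .assert(is(profile, "ConcentrationProfile"),
          "profile must be a ConcentrationProfile")
  x <- positions(profile); y <- concentrations(profile)
  .assert(max(y) > background,
          "degenerate profile: maximum intensity not above background")
  span <- x[length(x)] - x[1]
  tail <- y[x >= x[length(x)] - tailFrac * span]
  iSat <- quantile(tail, prob, names = FALSE)
  .assert(iSat > background, "saturation anchor not above background")
  z <- pmin(pmax((y - background) / (iSat - background), 0), 1)
  out <- ConcentrationProfile(x, z, time = profileTime(profile),
                              units = "relative")
  attr(out, "i_sat") <- iSat
  out
}

#' Per-section membrane-damage fraction from dye images
#'
#' The areal-intensity damage readout: in each zonal section, the summed
#' background-subtracted EthD-1 (membrane-damage) intensity divided by the
#' summed background-subtracted CellTracker (cell-distribution) intensity,
#' clipped to [0, 1]. Sections with no CellTracker signal are flagged NA.
#'
#' @param ethd1 EthD-1 [ChannelImage-class].
#' @param celltracker CellTracker [ChannelImage-class]; must share
#'   geometry and mask with \code{ethd1}.
#' @param sections data.frame from [sectionChannel()].
#' @param backgroundE,backgroundC dye backgrounds; estimated from outside
#'   the mask when missing.
#' @return numeric vector of damage fractions, one per section (NA where
#'   undefined), with attribute \code{"flagged"} listing undefined
#'   sections.
#' @export
damageFractionBySection <- function(ethd1, celltracker, sections,
                                    backgroundE = NULL,
                                    backgroundC = NULL) {
  .assert(is(ethd1, "ChannelImage") && is(celltracker, "ChannelImage"),
          "dye images must be ChannelImage objects")
  .assert(identical(dim(ethd1@pixels), dim(celltracker@pixels)) &&
            identical(ethd1@mask, celltracker@mask) &&
            isTRUE(all.equal(ethd1@pixelSize, celltracker@pixelSize)),
          "dye images must share geometry and mask")
  if (is.null(backgroundE)) backgroundE <- estimateBackground(ethd1)
  if (is.null(backgroundC)) backgroundC <- estimateBackground(celltracker)
  xcol <- (seq_len(ncol(ethd1@pixels)) - 0.5) * ethd1@pixelSize
  eSub <- pmax(ethd1@pixels - backgroundE, 0) * ethd1@mask
  cSub <- pmax(celltracker@pixels - backgroundC, 0) * celltracker@mask
  frac <- vapply(seq_len(nrow(sections)), function(i) {
    cols <- xcol >= sections$x_lo[i] & xcol <= sections$x_hi[i]
    eSum <- sum(eSub[, cols])
    cSum <- sum(cSub[, cols])
    if (cSum <= 0) return(NA_real_)
    min(max(eSum / cSum, 0), 1)
  }, numeric(1))
  attr(frac, "flagged") <- which(is.na(frac))
  frac
}
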