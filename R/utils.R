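# internal helpers shared across modules

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# seconds in a day; times are cm/s internally, days at the interface
.DAY <- 86400

#' Construct a ConcentrationProfile
#'
#' @param positions numeric, axial positions in cm (strictly increasing).
#' @param concentrations numeric, one value per position.
#' @param time time point in seconds (see \code{days}).
#' @param days alternatively, time in days; used if \code{time} is missing.
#' @param units \code{"uM"} or \code{"relative"}.
#' @return a [ConcentrationProfile-class].
#' @examples
#' ConcentrationProfile(seq(0, 9, length.out = 11),
#'                      seq(0, 9, length.out = 11), days = 7)
#' @export
ConcentrationProfile <- function(positions, concentrations, time = NULL,
                                 days = NULL, units = "uM") {
  if (is.null(time)) time <- if (is.null(days)) 0 else days * .DAY
  new("ConcentrationProfile", positions = as.numeric(positions),
      concentrations = as.numeric(concentrations),
      time = as.numeric(time), units = units)
}

#' Construct channel geometry
#'
#' Defaults follow the physical channel: a 9 cm long, 5 mm diameter
#' polyolefin tube discretized on 901 axial grid points.
#'
#' @param length channel length in cm (> 0).
#' @param diameter channel diameter in cm (> 0).
#' @param nGrid number of axial grid points (>= 3).
#' @return a list with class \code{"ChannelGeometry"}.
#' @examples
#' channelGeometry()
#' @export
channelGeometry <- function(length = 9, diameter = 0.5, nGrid = 901L) {
  .assert(is.numeric(length) && length > 0, "channel length must be > 0")
  .assert(is.numeric(diameter) && diameter > 0, "diameter must be > 0")
  .assert(nGrid >= 3, "nGrid must be at least 3")
  structure(list(length = length, diameter = diameter,
                 nGrid = as.integer(nGrid)),
            class = "ChannelGeometry")
}

#' Construct boundary conditions for the gradient solver
#'
#' The canonical setup holds 0.1\% DMSO medium (0 uM CHIR) at Inlet 1
#' (x = 0) and 9 uM CHIR at Inlet 2 (x = L). Daily medium renewal is
#' modelled as perfectly fixed reservoir concentrations.
#'
#' @param cInlet1 concentration held at x = 0, in uM (>= 0).
#' @param cInlet2 concentration held at x = L, in uM (>= 0).
#' @param regime boundary regime; only \code{"fixed_reservoirs"} is
#'   implemented.
#' @return a list with class \code{"BoundaryConditions"}.
#' @examples
#' boundaryConditions()
#' @export
boundaryConditions <- function(cInlet1 = 0, cInlet2 = 9,
                               regime = "fixed_reservoirs") {
  .assert(cInlet1 >= 0 && cInlet2 >= 0,
          "reservoir concentrations must be non-negative")
  regime <- match.arg(regime, "fixed_reservoirs")
  structure(list(cInlet1 = cInlet1, cInlet2 = cInlet2, regime = regime),
            class = "BoundaryConditions")
}

# run expr with a private RNG stream; leaves the caller's RNG untouched
.withSeed <- function(seed, expr) {
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "seed must be a single finite number")
  withr::with_seed(as.integer(seed), expr)
}

# derive a reproducible child seed from a base seed and a stream label,
# kept inside the 32-bit integer range
.childSeed <- function(seed, stream) {
  offs <- sum(utf8ToInt(as.character(stream)) * 131^(seq_along(
    utf8ToInt(as.character(stream))) %% 5))
  as.integer((as.numeric(seed) * 7919 + offs) %% .Machine$integer.max)
}
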