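# Plain-text interchange: profile CSV (position_cm, concentration_uM,
# time_days), viability CSV, qPCR Ct CSV and ASCII PGM (P2) images.
# Image I/O uses the portable greymap text format because it round-trips
# 16-bit single-channel rasters without any binary dependency.

#' Read / write a concentration profile as CSV
#'
#' @param path CSV path with header
#'   \code{position_cm,concentration_uM,time_days}.
#' @return [ConcentrationProfile-class] (read) or the path, invisibly
#'   (write).
#' @export
readConcentrationProfile <- function(path) {
  df <- read.csv(path)
  .assert(all(c("position_cm", "concentration_uM", "time_days") %in%
                names(df)),
          "profile CSV needs position_cm, concentration_uM, time_days")
  ConcentrationProfile(df$position_cm, df$concentration_uM,
                       days = df$time_days[1])
}

#' @rdname readConcentrationProfile
#' @param profile a [ConcentrationProfile-class].
#' @export
writeConcentrationProfile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a viability table as CSV
#'
#' Columns: \code{drug}, \code{condition}, \code{dose}, \code{unit},
#' \code{replicate}, \code{viability_pct}. The in-memory representation
#' uses \code{viability} (the column [fit4PL()] reads); the file format
#' uses the explicit \code{viability_pct} header.
#'
#' @param path CSV path.
#' @return data.frame (read) or the path, invisibly (write).
#' @export
readViabilityTable <- function(path) {
  df <- read.csv(path)
  .assert("viability_pct" %in% names(df),
          "viability CSV needs a viability_pct column")
  names(df)[names(df) == "viability_pct"] <- "viability"
  df
}

#' @rdname readViabilityTable
#' @param table a viability data.frame (e.g. from [genDoseResponse()]).
#' @export
writeViabilityTable <- function(table, path) {
  out <- table
  names(out)[names(out) == "viability"] <- "viability_pct"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a qPCR Ct table as CSV
#'
#' Columns: \code{sample}, \code{group}, \code{gene}, \code{ct}.
#'
#' @param path CSV path.
#' @return data.frame (read) or the path, invisibly (write).
#' @export
readCtTable <- function(path) {
  df <- read.csv(path)
  .assert(all(c("sample", "group", "gene", "ct") %in% names(df)),
          "Ct CSV needs sample, group, gene, ct")
  df
}

#' @rdname readCtTable
#' @param ct a Ct data.frame (e.g. from [genQpcrCt()]).
#' @export
writeCtTable <- function(ct, path) {
  write.csv(ct, path, row.names = FALSE)
  invisible(path)
}

#' Write a zonal viability surface as CSV
#'
#' Long format: \code{drug}, \code{section}, \code{dose}, \code{unit},
#' \code{viability_pct}.
#'
#' @param surface a [ZonalViabilitySurface-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeViabilitySurface <- function(surface, path) {
  .assert(is(surface, "ZonalViabilitySurface"),
          "surface must be a ZonalViabilitySurface")
  v <- viability(surface)
  df <- data.frame(
    drug = surface@drug,
    section = rep(sections(surface)$section, times = ncol(v)),
    dose = rep(surface@doses, each = nrow(v)),
    unit = surface@doseUnit,
    viability_pct = as.vector(v)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a channel image as ASCII PGM (P2)
#'
#' Portable greymap, plain-text variant: single-channel up-to-16-bit
#' rasters with no binary dependency. The mask, if given, is written as a
#' second PGM with maxval 1.
#'
#' @param path PGM path.
#' @param dye dye label for the reconstructed [ChannelImage-class].
#' @param pixelSize cm per pixel.
#' @param maskPath optional companion mask PGM.
#' @return [ChannelImage-class] (read) or the path, invisibly (write).
#' @export
readChannelImagePGM <- function(path, dye, pixelSize = 0.01,
                                maskPath = NULL) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  .assert(toks[1] == "P2", "only ASCII PGM (P2) is supported")
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  .assert(length(vals) == nr * nc, "PGM pixel count mismatch")
  px <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- NULL
  if (!is.null(maskPath)) {
    m <- readChannelImagePGM(maskPath, dye = dye, pixelSize = pixelSize)
    mask <- m@pixels > 0
  }
  channelImage(px, dye, pixelSize, mask)
}

#' @rdname readChannelImagePGM
#' @param img a [ChannelImage-class].
#' @param maxval PGM maximum value (default 65535, 16-bit).
#' @export
writeChannelImagePGM <- function(img, path, maskPath = NULL,
                                 maxval = 65535L) {
  .assert(is(img, "ChannelImage"), "img must be a ChannelImage")
  px <- round(pmin(pmax(img@pixels, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxval)),
             con)
  write(t(px), con, ncolumns = min(ncol(px), 16))
  if (!is.null(maskPath)) {
    m <- channelImage(matrix(as.numeric(img@mask), nrow(px), ncol(px)),
                      dye = img@dye, pixelSize = img@pixelSize)
    writeChannelImagePGM(m, maskPath, maxval = 1L)
  }
  invisible(path)
}
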