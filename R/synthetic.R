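# --- seeded generators -----------------------------------------------------
# Every generator is a pure function of (preset, arguments, seed): identical
# calls give bit-identical output and the caller's RNG state is untouched.

.conditionIC50 <- function(preset, condition, chir) {
  switch(condition,
    untreated = preset@ic50[["untreated"]],
    CHIR_9uM = preset@ic50[["chir9"]],
    custom = {
      .assert(!is.null(chir) && chir >= 0,
              "custom condition needs a non-negative chir (uM)")
      localIC50(preset, chir)
    },
    stop("unknown condition '", condition, "'", call. = FALSE))
}

#' Generate a synthetic plate dose-response viability table
#'
#' Emulates the CCK-8 plate assay: two-fold dilutions from the preset's top
#' dose, replicate viabilities drawn as 4PL(dose; preset truth) plus
#' Gaussian noise (default sd 5 percentage points), clipped at 0, with
#' dose-0 controls centred on the top asymptote.
#'
#' @param preset a [SyntheticPreset-class] or preset name.
#' @param condition \code{"untreated"}, \code{"CHIR_9uM"} or
#'   \code{"custom"} (with \code{chir}).
#' @param chir CHIR concentration in uM for the custom condition.
#' @param nDoses number of two-fold dilutions from the top dose (default 8).
#' @param nReps replicates per dose (default 6).
#' @param seed RNG seed (required; generators are deterministic).
#' @param noiseSd viability noise sd in \% points; defaults to the preset's.
#' @return data.frame with columns \code{drug}, \code{condition},
#'   \code{dose}, \code{unit}, \code{replicate}, \code{viability}.
#' @examples
#' tbl <- genDoseResponse("table1_bromobenzene", "CHIR_9uM", seed = 1)
#' ic50(fit4PL(tbl))
#' @export
genDoseResponse <- function(preset, condition = c("untreated", "CHIR_9uM",
                                                  "custom"),
                            chir = NULL, nDoses = 8, nReps = 6, seed,
                            noiseSd = NULL) {
  if (is.character(preset)) preset <- getPreset(preset)
  .assert(is(preset, "SyntheticPreset"), "preset must be a SyntheticPreset")
  condition <- match.arg(condition)
  if (is.null(noiseSd)) noiseSd <- preset@noise$viability_sd
  ic <- .conditionIC50(preset, condition, chir)
  doses <- c(0, preset@plateTopDose / 2^((nDoses - 1):0))
  truth <- .fourPL(doses, preset@top, preset@bottom, log10(ic),
                   preset@hill)
  .withSeed(seed, {
    tbl <- expand.grid(replicate = seq_len(nReps), dose = doses)
    mu <- truth[match(tbl$dose, doses)]
    tbl$viability <- pmax(mu + rnorm(nrow(tbl), 0, noiseSd), 0)
    data.frame(drug = preset@drug, condition = condition,
               dose = tbl$dose, unit = preset@doseUnit,
               replicate = tbl$replicate, viability = tbl$viability)
  })
}

#' Generate a synthetic sectioned channel screen
#'
#' Emulates the 6-section channel screening experiment: the day-7 CHIR
#' gradient is solved with the preset's effective diffusivity, the channel
#' is sectioned, and each section's viability at each dose is drawn from
#' the 4PL with the section-local IC50 (shared shape) plus Gaussian noise.
#'
#' @param preset a [SyntheticPreset-class] or preset name.
#' @param geom,bc channel geometry and boundary conditions.
#' @param n number of sections (default 6).
#' @param nDoses two-fold dilutions from the preset's channel top dose.
#' @param nReps replicate channels per dose (default 6).
#' @param seed RNG seed (required).
#' @param noiseSd viability noise sd; defaults to the preset's.
#' @return list: \code{screen} (data.frame section/dose/replicate/
#'   viability), \code{sections} (from [sectionChannel()]), \code{profile},
#'   \code{truthIC50} (per-section ground truth).
#' @examples
#' scr <- genZonalScreen("table1_apap", seed = 1)
#' head(scr$screen)
#' @export
genZonalScreen <- function(preset, geom = channelGeometry(),
                           bc = boundaryConditions(), n = 6, nDoses = 8,
                           nReps = 6, seed, noiseSd = NULL) {
  if (is.character(preset)) preset <- getPreset(preset)
  .assert(is(preset, "SyntheticPreset"), "preset must be a SyntheticPreset")
  if (is.null(noiseSd)) noiseSd <- preset@noise$viability_sd
  prof <- solveProfile(geom, bc, D = preset@gradient$D,
                       time = preset@gradient$time)
  secs <- sectionChannel(prof, n)
  truthIC50 <- localIC50(preset, secs$mean_chir)
  doses <- c(0, preset@channelTopDose / 2^((nDoses - 1):0))
  grid <- expand.grid(replicate = seq_len(nReps), dose = doses,
                      section = secs$section)
  mu <- .fourPL(grid$dose, preset@top, preset@bottom,
                log10(truthIC50[grid$section]), preset@hill)
  screen <- .withSeed(seed, {
    data.frame(drug = preset@drug, section = grid$section,
               dose = grid$dose, unit = preset@doseUnit,
               replicate = grid$replicate,
               viability = pmax(mu + rnorm(nrow(grid), 0, noiseSd), 0))
  })
  list(screen = screen, sections = secs, profile = prof,
       truthIC50 = truthIC50)
}

#' Render synthetic channel dye images
#'
#' Renders the ChemiDoc-style image triple for one channel at one drug
#' dose: \code{chir_uv} encodes the solved CHIR gradient as column
#' intensity, \code{celltracker} a spatially uniform cell signal with
#' multiplicative speckle, and \code{ethd1} the CellTracker signal scaled
#' by the local damage fraction 1 - V(dose; local IC50)/top. All three
#' share one mask (channel block surrounded by a background margin) and
#' all noise is seeded.
#'
#' @param preset a [SyntheticPreset-class] or preset name.
#' @param geom,bc channel geometry and boundary conditions.
#' @param time gradient age in seconds; defaults to the preset's (day 7).
#' @param dose drug dose driving the damage channel (preset dose units).
#' @param seed RNG seed (required).
#' @param pixelSize cm per pixel (default 0.01).
#' @param channelRows,margin channel thickness and background margin, px.
#' @param bg,sat background and saturation intensity levels (a.u.).
#' @param cellLevel mean CellTracker signal above background (a.u.).
#' @param speckleSd relative sd of the CellTracker speckle (default 0.1).
#' @param damageScale multiplier on the damage fraction (0 renders an
#'   undamaged channel).
#' @param noiseFrac additive Gaussian noise sd as a fraction of the
#'   dynamic range; defaults to the preset's.
#' @return named list of three [ChannelImage-class] objects
#'   (\code{chir_uv}, \code{celltracker}, \code{ethd1}) plus the ground
#'   truth: \code{profile} and per-column \code{damage}.
#' @examples
#' imgs <- genChannelImages("table1_apap", dose = 10, seed = 1)
#' imgs$chir_uv
#' @export
genChannelImages <- function(preset, geom = channelGeometry(),
                             bc = boundaryConditions(), time = NULL,
                             dose = 0, seed, pixelSize = 0.01,
                             channelRows = 50L, margin = 10L,
                             bg = 500, sat = 20000, cellLevel = 12000,
                             speckleSd = 0.1, damageScale = 1,
                             noiseFrac = NULL) {
  if (is.character(preset)) preset <- getPreset(preset)
  .assert(is(preset, "SyntheticPreset"), "preset must be a SyntheticPreset")
  if (is.null(time)) time <- preset@gradient$time
  if (is.null(noiseFrac)) noiseFrac <- preset@noise$image_noise_frac
  .assert(dose >= 0, "dose must be non-negative")
  nx <- round(geom$length / pixelSize)
  xMid <- (seq_len(nx) - 0.5) * pixelSize
  prof <- solveProfile(geom, bc, D = preset@gradient$D, time = time)
  cMid <- approx(positions(prof), concentrations(prof), xout = xMid,
                 rule = 2)$y
  rel <- cMid / max(bc$cInlet2, max(cMid))
  damage <- damageScale *
    (1 - .fourPL(rep(dose, length(cMid)), preset@top, preset@bottom,
                 log10(localIC50(preset, cMid)), preset@hill) /
       preset@top)
  nr <- channelRows + 2L * margin
  nc <- nx + 2L * margin
  mask <- matrix(FALSE, nr, nc)
  mask[margin + seq_len(channelRows), margin + seq_len(nx)] <- TRUE
  noiseSd <- noiseFrac * (sat - bg)
  .withSeed(seed, {
    base <- matrix(bg, nr, nc)
    uv <- ct <- ed <- base
    chirSignal <- matrix(rep((sat - bg) * rel, each = channelRows),
                         channelRows, nx)
    uv[mask] <- bg + chirSignal
    speckle <- matrix(pmax(1 + rnorm(channelRows * nx, 0, speckleSd), 0),
                      channelRows, nx)
    ctSignal <- cellLevel * speckle
    ct[mask] <- bg + ctSignal
    edSignal <- ctSignal * matrix(rep(damage, each = channelRows),
                                  channelRows, nx)
    ed[mask] <- bg + edSignal
    uv <- pmax(uv + rnorm(length(uv), 0, noiseSd), 0)
    ct <- pmax(ct + rnorm(length(ct), 0, noiseSd), 0)
    ed <- pmax(ed + rnorm(length(ed), 0, noiseSd), 0)
    list(
      chir_uv = channelImage(uv, "chir_uv", pixelSize, mask),
      celltracker = channelImage(ct, "celltracker", pixelSize, mask),
      ethd1 = channelImage(ed, "ethd1", pixelSize, mask),
      profile = prof, damage = damage
    )
  })
}

#' Generate synthetic qPCR Ct tables for a CYP induction preset
#'
#' Draws Ct values encoding the calibrated fold induction against the 18S
#' reference: the reference sits at a fixed Ct (plus noise) in every
#' sample; the target gene sits at a baseline Ct in controls and at
#' baseline - log2(fold) in treated samples, each plus Gaussian noise
#' (default sd 0.2 cycles).
#'
#' With the defaults (3 replicates per group, two noisy genes per sample),
#' the group ddCt has sd sqrt(4 * ctSd^2 / nReps) ~ 0.23 cycles, so the
#' recovered fold is within about +/-20\% of truth (1 sd); this is the
#' generator's documented tolerance band.
#'
#' @param preset a qPCR preset name (e.g. \code{"cyp1a2_chir9"}) or the
#'   list returned by [getPreset()] for one.
#' @param chir treated-group CHIR concentration, uM; defaults to the
#'   preset's.
#' @param nReps samples per group (default 3).
#' @param seed RNG seed (required).
#' @param ctSd Ct noise sd in cycles (default 0.2).
#' @param refCt reference-gene Ct (default 12, 18S is abundant).
#' @param baselineCt control-group target Ct (default 25).
#' @param curve optional [InductionCurve-class] overriding the preset's.
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{gene}, \code{ct}.
#' @examples
#' ct <- genQpcrCt("cyp1a2_chir9", seed = 7)
#' ddctFoldChange(ct, "CYP1A2")$fold  # close to 20
#' @export
genQpcrCt <- function(preset, chir = NULL, nReps = 3, seed, ctSd = 0.2,
                      refCt = 12, baselineCt = 25, curve = NULL) {
  if (is.character(preset)) preset <- getPreset(preset)
  .assert(is.list(preset) && !is.null(preset$cyp),
          "preset must name a qPCR induction preset")
  if (is.null(chir)) chir <- preset$chir
  if (is.null(curve)) curve <- inductionCurve(preset$cyp)
  fold <- inductionAt(curve, chir)
  gene <- preset$cyp
  .withSeed(seed, {
    mkGroup <- function(grp, prefix, targetCt) {
      samples <- paste0(prefix, seq_len(nReps))
      rbind(
        data.frame(sample = samples, group = grp, gene = "18S",
                   ct = refCt + rnorm(nReps, 0, ctSd)),
        data.frame(sample = samples, group = grp, gene = gene,
                   ct = targetCt + rnorm(nReps, 0, ctSd))
      )
    }
    rbind(mkGroup("control", "ctrl_", baselineCt),
          mkGroup("treated", "chir_", baselineCt - log2(fold)))
  })
}

#' Generate a synthetic log2 expression matrix with spiked DEGs
#'
#' Gaussian log2 intensities around gene-specific baselines, with a known
#' subset of genes shifted by +/- log2fc in the treated group: the test bed
#' for the 2-fold / P < 0.01 differential-expression filter.
#'
#' @param nGenes total genes (default 10000).
#' @param nDeg number of spiked genes (default 300; must be < nGenes).
#' @param log2fc absolute spiked shift on the log2 scale (default 1.5).
#' @param sd within-group noise sd on the log2 scale (default 0.3).
#' @param nPerGroup samples per group (default 4).
#' @param seed RNG seed (required).
#' @return list: \code{se} (a \code{SummarizedExperiment} with assay
#'   \code{log2}, \code{colData$group} and logical
#'   \code{rowData$true_deg}), \code{truth} (spiked gene names).
#' @examples
#' sim <- genExpressionMatrix(nGenes = 500, nDeg = 20, seed = 11)
#' sum(SummarizedExperiment::rowData(sim$se)$true_deg)
#' @export
genExpressionMatrix <- function(nGenes = 10000, nDeg = 300, log2fc = 1.5,
                                sd = 0.3, nPerGroup = 4, seed) {
  .assert(nDeg < nGenes, "nDeg must be smaller than nGenes")
  .assert(nPerGroup >= 2, "need at least 2 samples per group")
  .withSeed(seed, {
    genes <- sprintf("gene%05d", seq_len(nGenes))
    base <- rnorm(nGenes, 8, 1)
    n <- 2 * nPerGroup
    mat <- matrix(rnorm(nGenes * n, 0, sd), nGenes, n) + base
    group <- rep(c("control", "treated"), each = nPerGroup)
    degIdx <- sort(sample.int(nGenes, nDeg))
    signs <- sample(c(-1, 1), nDeg, replace = TRUE)
    mat[degIdx, group == "treated"] <-
      mat[degIdx, group == "treated"] + signs * log2fc
    rownames(mat) <- genes
    colnames(mat) <- paste0(group, rep(seq_len(nPerGroup), 2))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2 = mat),
      colData = S4Vectors::DataFrame(group = group),
      rowData = S4Vectors::DataFrame(
        true_deg = seq_len(nGenes) %in% degIdx,
        spike_sign = ifelse(seq_len(nGenes) %in% degIdx,
                            signs[match(seq_len(nGenes), degIdx)], 0))
    )
    list(se = se, truth = genes[degIdx])
  })
}
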