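#' Relative quantification by the 2^-ddCt method
#'
#' Computes fold change of a target gene between treated and control groups
#' from qPCR Ct values with a reference gene (18S rRNA by default):
#' per-sample dCt = Ct_gene - Ct_ref, ddCt = mean dCt(treated) -
#' mean dCt(control), fold = 2^-ddCt. Per-treated-sample folds against the
#' control mean dCt are returned alongside the group estimate.
#'
#' @param ct data.frame with columns \code{sample}, \code{group}
#'   (\code{"control"} / \code{"treated"}), \code{gene}, \code{ct}
#'   (cycles, finite). Every sample must carry the reference gene.
#' @param gene target gene name.
#' @param reference reference gene name (default \code{"18S"}).
#' @return list with \code{fold} (group fold change), \code{ddct},
#'   \code{sampleFolds} (per treated sample).
#' @examples
#' ct <- rbind(
#'   data.frame(sample = paste0("c", 1:2), group = "control",
#'              gene = "18S", ct = 12),
#'   data.frame(sample = paste0("c", 1:2), group = "control",
#'              gene = "CYP1A2", ct = 25),
#'   data.frame(sample = paste0("t", 1:2), group = "treated",
#'              gene = "18S", ct = 12),
#'   data.frame(sample = paste0("t", 1:2), group = "treated",
#'              gene = "CYP1A2", ct = 24))
#' ddctFoldChange(ct, "CYP1A2")$fold  # 2: one cycle earlier = doubling
#' @export
ddctFoldChange <- function(ct, gene, reference = "18S") {
  .assert(is.data.frame(ct) &&
            all(c("sample", "group", "gene", "ct") %in% names(ct)),
          "ct must have columns sample, group, gene, ct")
  .assert(all(is.finite(ct$ct)), "Ct values must be finite")
  .assert(all(ct$group %in% c("control", "treated")),
          "group must be 'control' or 'treated'")
  dctOf <- function(grp) {
    sub <- ct[ct$group == grp, , drop = FALSE]
    tgt <- sub[sub$gene == gene, , drop = FALSE]
    ref <- sub[sub$gene == reference, , drop = FALSE]
    .assert(nrow(tgt) > 0, sprintf("gene '%s' missing in %s group",
                                   gene, grp))
    .assert(nrow(ref) > 0, sprintf("reference '%s' missing in %s group",
                                   reference, grp))
    refCt <- setNames(ref$ct, ref$sample)
    .assert(all(tgt$sample %in% names(refCt)),
            "every sample needs a reference-gene Ct")
    setNames(tgt$ct - refCt[tgt$sample], tgt$sample)
  }
  dctC <- dctOf("control")
  dctT <- dctOf("treated")
  ddct <- mean(dctT) - mean(dctC)
  list(fold = 2^(-ddct), ddct = ddct,
       sampleFolds = 2^(-(dctT - mean(dctC))))
}

.assayGroups <- function(mat, group) {
  if (is(mat, "SummarizedExperiment")) {
    group <- SummarizedExperiment::colData(mat)$group
    mat <- SummarizedExperiment::assay(mat)
  }
  .assert(!is.null(group), "group labels required")
  group <- as.character(group)
  .assert(all(group %in% c("control", "treated")),
          "group labels must be 'control' or 'treated'")
  .assert(sum(group == "control") >= 2 && sum(group == "treated") >= 2,
          "each group needs at least 2 samples")
  .assert(!anyNA(mat), "expression matrix must not contain missing values")
  list(mat = as.matrix(mat), group = group)
}

#' Fold-change / P-value differential-expression filter
#'
#' The array-style DEG filter: per-gene Welch two-sample t-test on log2
#' intensities, selecting genes with an absolute fold change of at least
#' \code{fcThreshold} (i.e. |log2 FC| >= log2(fcThreshold), boundary
#' inclusive) and P below \code{pThreshold}, with no multiplicity
#' correction.
#'
#' @param mat genes x samples matrix of log2 intensities, or a
#'   \code{SummarizedExperiment} whose \code{colData} has a \code{group}
#'   column.
#' @param group per-sample labels (\code{"control"} / \code{"treated"});
#'   taken from \code{colData} for a SummarizedExperiment.
#' @param fcThreshold linear fold-change threshold (default 2).
#' @param pThreshold P-value threshold (default 0.01, strict).
#' @return data.frame with one row per gene: \code{gene}, \code{log2fc}
#'   (treated minus control), \code{p}, \code{selected}.
#' @examples
#' sim <- genExpressionMatrix(nGenes = 200, nDeg = 10, seed = 1)
#' res <- degFilter(sim$se)
#' table(res$selected)
#' @export
degFilter <- function(mat, group = NULL, fcThreshold = 2,
                      pThreshold = 0.01) {
  ag <- .assayGroups(mat, group)
  x <- ag$mat[, ag$group == "treated", drop = FALSE]
  y <- ag$mat[, ag$group == "control", drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  sq <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(sq)
  dfw <- sq^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(tstat), dfw)
  # degenerate zero-variance genes: identical groups are not DE, exact
  # shifts are (the t statistic is +-Inf, p -> 0)
  zeroVar <- sq == 0
  p[zeroVar & (mx - my) == 0] <- 1
  p[zeroVar & (mx - my) != 0] <- 0
  lfc <- mx - my
  genes <- rownames(ag$mat)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(ag$mat)))
  data.frame(
    gene = genes, log2fc = unname(lfc), p = unname(p),
    selected = unname(abs(lfc) >= log2(fcThreshold) & p < pThreshold)
  )
}

#' Write a DEG report
#'
#' @param deg result of [degFilter()].
#' @param path output TSV path (columns gene, log2fc, p, selected).
#' @return the path, invisibly.
#' @export
writeDegReport <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
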