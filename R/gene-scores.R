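#' Map variants to gene regions by a flanking window
#'
#' A variant belongs to a gene iff its position lies in
#' `[start - window, end + window]` (1-based inclusive; boundaries
#' included), so a variant between two nearby genes belongs to both.
#' Genes with no member variant are dropped; genes overlapping the HLA
#' region are excluded by default (the major histocompatibility complex's
#' extreme LD makes its gene scores unreliable).
#'
#' @param annotation data.frame: `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive internal convention; use [readBedAnnotation()] for BED input).
#' @param variants data.frame with `variant_id`, `chrom`, `pos`.
#' @param window Flank in bp (default 50000).
#' @param excludeHla Drop genes overlapping `hlaRegion`.
#' @param hlaRegion List `(chrom, start, end)`; default the hg19 MHC span.
#' @return Named list of gene regions, each a list
#'   `(gene, chrom, start, end, window, variants)`; attribute `nHlaExcluded`
#'   counts removed HLA genes.
#' @export
mapVariantsToGenes <- function(annotation, variants, window = 50000,
                               excludeHla = TRUE,
                               hlaRegion = list(chrom = "chr6",
                                                start = 28477797,
                                                end = 33448354)) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(annotation)),
            all(c("variant_id", "chrom", "pos") %in% names(variants)))
  if (any(annotation$start > annotation$end)) {
    grpmError("annotation has start > end", "formatError")
  }
  nHla <- 0L
  if (excludeHla) {
    hla <- annotation$chrom == hlaRegion$chrom &
      annotation$start <= hlaRegion$end & annotation$end >= hlaRegion$start
    nHla <- sum(hla)
    annotation <- annotation[!hla, , drop = FALSE]
  }
  genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(1, annotation$start - window),
                     annotation$end + window)
  )
  vpos <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos,
                                                  variants$pos))
  hits <- GenomicRanges::findOverlaps(genes, vpos)
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    vs <- variants$variant_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    if (!length(vs)) return(NULL)
    list(gene = annotation$gene[i], chrom = annotation$chrom[i],
         start = annotation$start[i], end = annotation$end[i],
         window = window, variants = vs)
  })
  names(out) <- annotation$gene
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "nHlaExcluded") <- nHla
  out
}

#' LD correlation matrix for a set of variants from a reference panel
#'
#' Pearson correlation of reference-panel dosages, the standard plug-in LD
#' estimate for summary-statistic methods.
#'
#' @param panel Individuals-by-variants dosage matrix (reference panel).
#' @param variantIds Variants to correlate (must be panel columns).
#' @return Symmetric correlation matrix with unit diagonal. Monomorphic
#'   panel variants get zero off-diagonal correlation.
#' @export
panelLdMatrix <- function(panel, variantIds) {
  miss <- setdiff(variantIds, colnames(panel))
  if (length(miss)) {
    grpmError(paste("variants absent from LD panel:",
                    paste(head(miss, 5), collapse = ", ")), "schemaError")
  }
  x <- panel[, variantIds, drop = FALSE]
  sds <- apply(x, 2, sd)
  ld <- suppressWarnings(cor(x))
  ld[is.na(ld)] <- 0
  diag(ld) <- 1
  ld
}

## internal: square root of an LD matrix, repairing non-PSD input by
## eigenvalue clipping at 1e-8 (with a warning), per contract.
ldSqrt <- function(ld) {
  ev <- eigen(ld, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) < -1e-8) {
    warning("LD matrix not positive semi-definite; clipping eigenvalues")
  }
  lam <- pmax(lam, 1e-8)
  list(sqrtMat = ev$vectors %*% diag(sqrt(lam), length(lam)), lambda = lam)
}

## internal: adaptive Monte Carlo tail probability. `drawStat(B)` returns B
## draws of the null statistic; escalates draws x10 until >= 50 exceedances
## of `T` or the draw cap, then reports the (k+1)/(n+1) estimate.
mcTailP <- function(T, drawStat, mcMin = 1e4, mcCap = 1e7) {
  target <- mcMin
  total <- 0
  exceed <- 0
  repeat {
    while (total < target) {
      B <- min(1e6, target - total)
      exceed <- exceed + sum(drawStat(B) >= T)
      total <- total + B
    }
    if (exceed >= 50 || total >= mcCap) break
    target <- min(total * 10, mcCap)
  }
  list(p = permP(exceed, total), draws = total)
}

## internal: shared argument checks for the two gene statistics
checkGeneScoreArgs <- function(variantPs, ld) {
  m <- length(variantPs)
  if (m == 0) grpmError("empty variant set", "emptyGeneError")
  checkProb(variantPs, "variantPs")
  if (!is.matrix(ld) || any(dim(ld) != m) || max(abs(ld - t(ld))) > 1e-8 ||
      max(abs(diag(ld) - 1)) > 1e-8) {
    grpmError("ld must be a symmetric unit-diagonal matrix matching variantPs",
              "schemaError")
  }
  m
}

#' LD-aware gene P value from the maximum chi-squared statistic
#'
#' The gene statistic is `T = max_i qchisq(1 - p_i, 1)`, the strongest
#' single-variant association in the gene window. Its null distribution —
#' the maximum of squared coordinates of a multivariate normal with the
#' reference-panel LD as covariance — is evaluated by adaptive Monte Carlo:
#' at least `mcMin` draws, escalated tenfold until at least 50 exceedances
#' are seen or `mcCap` draws are spent. The reported P uses the
#' `(k + 1) / (n + 1)` estimator and is therefore never exactly zero. A
#' single-variant gene is exact (`P = p_1`). For associations so extreme
#' that the draw cap saturates without exceedances, the union (Bonferroni)
#' bound `m * min(p)` is reported when it is tighter than the Monte Carlo
#' floor, preserving the dynamic range of genome-wide-significant genes.
#'
#' @param variantPs Per-variant two-sided P values in `(0, 1]`.
#' @param ld LD correlation matrix (see [panelLdMatrix()]).
#' @param gene Gene id recorded in the result.
#' @param mcMin,mcCap Minimum draws and draw cap.
#' @param seed Integer seed.
#' @return One-row data.frame: `gene`, `statistic`, `p`, `heat`
#'   (`-log10(p)`), `n_variants`, `mc_draws`.
#' @examples
#' genePMaxChisq(c(0.05, 0.5), diag(2), seed = 1)
#' @export
genePMaxChisq <- function(variantPs, ld = diag(length(variantPs)),
                          gene = "gene", mcMin = 1e4, mcCap = 1e7,
                          seed = 1L) {
  m <- checkGeneScoreArgs(variantPs, ld)
  T <- max(qchisq(variantPs, 1, lower.tail = FALSE))
  if (m == 1) {
    res <- list(p = variantPs[1], draws = 0)
  } else {
    A <- ldSqrt(ld)$sqrtMat
    set.seed(seed)
    res <- mcTailP(T, function(B) {
      z2 <- (A %*% matrix(rnorm(m * B), m, B))^2
      s <- z2[1, ]
      for (i in seq_len(m)[-1]) s <- pmax(s, z2[i, ])
      s
    }, mcMin, mcCap)
    ## analytic tail extension: when the draw cap saturates without enough
    ## exceedances the floored estimate is only an upper limit of MC
    ## resolution; the union bound m * p_min is then a tighter upper bound
    ## on the true tail (and asymptotically exact for extreme maxima), so
    ## the smaller of the two is reported. Never zero by construction.
    bonf <- m * min(variantPs)
    if (res$draws >= mcCap && bonf < res$p) res$p <- bonf
  }
  data.frame(gene = gene, statistic = T, p = res$p,
             heat = -log10(res$p), n_variants = m, mc_draws = res$draws,
             stringsAsFactors = FALSE)
}

#' LD-aware gene P value from the sum of chi-squared statistics
#'
#' The gene statistic is `T = sum_i qchisq(1 - p_i, 1)`, the average signal
#' across the gene. Under the null it is a weighted sum of independent 1-df
#' chi-squares with weights the eigenvalues of the LD matrix; the tail is
#' evaluated by the same adaptive Monte Carlo scheme as [genePMaxChisq()].
#'
#' @inheritParams genePMaxChisq
#' @return One-row data.frame as in [genePMaxChisq()].
#' @export
genePSumChisq <- function(variantPs, ld = diag(length(variantPs)),
                          gene = "gene", mcMin = 1e4, mcCap = 1e7,
                          seed = 1L) {
  m <- checkGeneScoreArgs(variantPs, ld)
  T <- sum(qchisq(variantPs, 1, lower.tail = FALSE))
  if (m == 1) {
    res <- list(p = variantPs[1], draws = 0)
  } else {
    lam <- ldSqrt(ld)$lambda
    set.seed(seed)
    res <- mcTailP(T, function(B) {
      colSums(lam * matrix(rnorm(m * B)^2, m, B))
    }, mcMin, mcCap)
  }
  data.frame(gene = gene, statistic = T, p = res$p,
             heat = -log10(res$p), n_variants = m, mc_draws = res$draws,
             stringsAsFactors = FALSE)
}

#' Gene scores for all genes from GWAS summary statistics
#'
#' Applies [genePMaxChisq()] (or [genePSumChisq()]) to every mapped gene,
#' estimating each gene's LD matrix from the reference panel. Per-gene seeds
#' derive deterministically from `seed` and the gene id, so results do not
#' depend on gene order.
#'
#' @param summary GWAS summary data.frame (from [runSurvivalGwas()]): needs
#'   `variant_id` and `p`.
#' @param regions Gene regions from [mapVariantsToGenes()].
#' @param panel Reference-panel dosage matrix.
#' @param stat `"max"` (default, the recommended statistic) or `"sum"`.
#' @param mcMin,mcCap Monte Carlo draw bounds per gene.
#' @param seed Integer seed.
#' @return data.frame with one row per scored gene: `gene`, `chrom`,
#'   `start`, `end`, `n_variants`, `statistic`, `p`, `heat`, `mc_draws`.
#' @export
geneScores <- function(summary, regions, panel, stat = c("max", "sum"),
                       mcMin = 1e4, mcCap = 1e7, seed = 1L) {
  stat <- match.arg(stat)
  fn <- if (stat == "max") genePMaxChisq else genePSumChisq
  rows <- lapply(regions, function(reg) {
    vs <- intersect(reg$variants, summary$variant_id)
    if (!length(vs)) return(NULL)
    ps <- summary$p[match(vs, summary$variant_id)]
    ld <- panelLdMatrix(panel, vs)
    sc <- fn(ps, ld, gene = reg$gene, mcMin = mcMin, mcCap = mcCap,
             seed = stageSeed(seed, reg$gene))
    cbind(sc[, "gene", drop = FALSE],
          data.frame(chrom = reg$chrom, start = reg$start, end = reg$end),
          sc[, c("n_variants", "statistic", "p", "heat", "mc_draws")])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Compare the max and sum gene statistics (QQ data and genomic inflation)
#'
#' Emits, for each statistic, the sorted observed `-log10` gene P values
#' against expected uniform quantiles, plus the genomic inflation factor
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`. The recommendation
#' (the statistic whose top-decile genes deviate more from the uniform
#' expectation, i.e. apparent power) is advisory and user-overridable.
#'
#' @param geneScoresMax,geneScoresSum Score data.frames over the same gene
#'   universe (columns `gene`, `p`).
#' @return List: `lambda` (named numeric), `qq` (named list of data.frames
#'   with `expected`/`observed` in -log10 units), `recommended`.
#' @export
chooseStatistic <- function(geneScoresMax, geneScoresSum) {
  shared <- intersect(geneScoresMax$gene, geneScoresSum$gene)
  qqOne <- function(p) {
    p <- sort(p)
    data.frame(expected = -log10(stats::ppoints(length(p))),
               observed = -log10(p))
  }
  pm <- geneScoresMax$p[match(shared, geneScoresMax$gene)]
  ps <- geneScoresSum$p[match(shared, geneScoresSum$gene)]
  lam <- function(p) median(qchisq(p, 1, lower.tail = FALSE)) /
    qchisq(0.5, 1, lower.tail = FALSE)
  topSignal <- function(p) {
    k <- max(1, floor(length(p) / 10))
    mean(sort(-log10(p), decreasing = TRUE)[seq_len(k)])
  }
  list(lambda = c(max = lam(pm), sum = lam(ps)),
       qq = list(max = qqOne(pm), sum = qqOne(ps)),
       recommended = if (topSignal(pm) >= topSignal(ps)) "max" else "sum")
}

#' Correlation between gene scores and network degree
#'
#' Ascertainment-bias diagnostic: well-studied genes have more recorded
#' interactions, so a positive correlation between score and degree would
#' flag study-bias leakage into the propagation input.
#'
#' @param scores Gene-score data.frame (`gene`, `heat`).
#' @param network Edge-list data.frame (`from`, `to`).
#' @return List: `r` (Pearson), `p` (two-sided), `n` genes used.
#' @export
degreeBiasCheck <- function(scores, network) {
  g <- igraph::graph_from_data_frame(network, directed = FALSE)
  deg <- igraph::degree(g)
  shared <- intersect(scores$gene, names(deg))
  if (length(shared) < 3) {
    grpmError("need >= 3 genes shared between scores and network",
              "schemaError")
  }
  x <- scores$heat[match(shared, scores$gene)]
  y <- deg[shared]
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = NA_real_,
                                            n = length(shared)))
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
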