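#' Correlate a module's PHS with genome-wide expression
#'
#' For each gene, the Pearson correlation between the PHS and that gene's
#' expression over patients present in both inputs (complete pairs). Genes
#' with zero expression variance are excluded (counted in an attribute).
#'
#' @param phs Named per-patient scores.
#' @param expression Patients-by-genes expression matrix (row names =
#'   patient ids).
#' @return data.frame (`gene`, `r`, `n`) sorted by `r` descending; attribute
#'   `nZeroVariance` counts excluded genes.
#' @export
downstreamScores <- function(phs, expression) {
  shared <- intersect(names(phs), rownames(expression))
  if (length(shared) < 3) grpmError("need >= 3 matched patients",
                                    "schemaError")
  x <- phs[shared]
  if (sd(x) == 0) grpmError("constant PHS", "degenerateScoreError")
  e <- expression[shared, , drop = FALSE]
  sds <- apply(e, 2, sd)
  zero <- sds == 0 | !is.finite(sds)
  e <- e[, !zero, drop = FALSE]
  r <- as.vector(cor(x, e))
  out <- data.frame(gene = colnames(e), r = r, n = length(shared),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r), ]
  rownames(out) <- NULL
  attr(out, "nZeroVariance") <- sum(zero)
  out
}

## internal: weighted Kolmogorov-Smirnov enrichment score of a gene set in
## a ranking. `stats` must be sorted decreasing; returns the signed maximum
## deviation of the running sum (hit increments proportional to
## |stat|^weight, miss decrements 1/(N - Nh)).
enrichmentScore <- function(stats, hitIdx, weight = 1) {
  N <- length(stats)
  Nh <- length(hitIdx)
  step <- rep(-1 / (N - Nh), N)
  w <- abs(stats[hitIdx])^weight
  if (sum(w) == 0) w <- rep(1, Nh)
  step[hitIdx] <- w / sum(w)
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Classic weighted-KS pre-ranked GSEA: for each gene set, the enrichment
#' score (ES) is the maximum deviation of the running sum over the ranking
#' (hit increments proportional to `|r|^weight`, misses `-1/(N - Nh)`).
#' Significance uses a gene-label permutation null with a sign-matched tail
#' and the `(k + 1) / (n + 1)` floor; NES divides ES by the mean magnitude
#' of same-sign permutation scores, and FDR q uses the standard pooled-NES
#' ratio estimator.
#'
#' @param ranking Named numeric vector (gene -> correlation), any order;
#'   genes must be unique.
#' @param geneSets Named list of character vectors (e.g. from [readGmt()]).
#' @param weight Running-sum weight exponent (default 1, classic GSEA).
#' @param nPerm Permutations per set (default 1000).
#' @param minSize,maxSize Set-size filter after intersecting with the
#'   ranking universe (defaults 15 and 500).
#' @param seed Integer seed (per-set seeds derive from it and the set name).
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `fdr`; empty (with a
#'   warning) when no set survives filtering.
#' @export
gseaPreranked <- function(ranking, geneSets, weight = 1, nPerm = 1000,
                          minSize = 15, maxSize = 500, seed = 1L) {
  if (anyDuplicated(names(ranking))) {
    grpmError("ranking has duplicated genes", "schemaError")
  }
  stats <- sort(ranking, decreasing = TRUE)
  N <- length(stats)
  sets <- lapply(geneSets, function(s) which(names(stats) %in% s))
  sizes <- vapply(sets, length, integer(1))
  keep <- sizes >= minSize & sizes <= maxSize & sizes < N
  if (!any(keep)) {
    warning("no gene set survives size filtering")
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), fdr = numeric()))
  }
  sets <- sets[keep]
  es <- vapply(sets, function(h) enrichmentScore(stats, h, weight),
               numeric(1))
  permNes <- vector("list", length(sets))
  nes <- p <- numeric(length(sets))
  for (i in seq_along(sets)) {
    set.seed(stageSeed(seed, names(sets)[i]))
    n <- length(sets[[i]])
    perm <- vapply(seq_len(nPerm), function(b) {
      enrichmentScore(stats, sort(sample.int(N, n)), weight)
    }, numeric(1))
    same <- perm[sign(perm) == sign(es[i])]
    nSame <- length(same)
    p[i] <- permP(sum(abs(same) >= abs(es[i])), max(nSame, 1))
    denom <- if (nSame) mean(abs(same)) else NA_real_
    nes[i] <- if (is.na(denom) || denom == 0) NA_real_ else es[i] / denom
    permNes[[i]] <- if (nSame) same / denom else numeric()
  }
  pool <- unlist(permNes)
  fdr <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    s <- sign(nes[i])
    poolSame <- pool[sign(pool) == s]
    obsSame <- nes[!is.na(nes) & sign(nes) == s]
    num <- if (length(poolSame)) mean(abs(poolSame) >= abs(nes[i])) else 0
    den <- mean(abs(obsSame) >= abs(nes[i]))
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, numeric(1))
  out <- data.frame(set = names(sets), size = vapply(sets, length,
                                                     integer(1)),
                    es = es, nes = nes, p = p, fdr = fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p, -abs(out$nes)), ]
}

#' Filter enrichment results on nominal P and FDR
#'
#' Default thresholds keep sets with nominal `P < 0.001` and `FDR < 0.05`;
#' a stricter display threshold (`fdrMax = 0.01`) is available for
#' headline-figure use.
#'
#' @param results data.frame from [gseaPreranked()].
#' @param pMax Nominal-P threshold (strict).
#' @param fdrMax FDR threshold (strict).
#' @return The significant subset of `results`.
#' @export
filterEnriched <- function(results, pMax = 0.001, fdrMax = 0.05) {
  results[!is.na(results$p) & results$p < pMax &
            !is.na(results$fdr) & results$fdr < fdrMax, , drop = FALSE]
}
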