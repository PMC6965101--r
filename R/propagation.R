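#' Build the insulated heat-diffusion operator of a network
#'
#' Restricts the undirected network to its largest connected component,
#' column-normalises the adjacency into the walk matrix `W` and computes the
#' insulated diffusion matrix `F = beta * (I - (1 - beta) W)^-1` by a dense
#' solve. `beta` is the restart (insulation) probability: `beta = 1` gives
#' `F = I` (no diffusion); smaller `beta` spreads heat further.
#'
#' @param network Edge-list data.frame (`from`, `to`).
#' @param beta Restart probability in `(0, 1]` (default 0.4).
#' @return A [DiffusionOperator-class].
#' @examples
#' net <- data.frame(from = "a", to = "b")
#' diffusionMatrix(buildDiffusion(net, beta = 0.5))  # [[2/3,1/3],[1/3,2/3]]
#' @export
buildDiffusion <- function(network, beta = 0.4) {
  if (beta <= 0 || beta > 1) grpmError("beta must lie in (0, 1]",
                                       "invalidConfigError")
  if (nrow(network) == 0) grpmError("empty network", "invalidConfigError")
  g <- igraph::simplify(igraph::graph_from_data_frame(network,
                                                      directed = FALSE))
  comp <- igraph::components(g)
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  g <- igraph::induced_subgraph(g, keep)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  genes <- rownames(A)
  W <- sweep(A, 2, colSums(A), "/")
  n <- length(genes)
  Fmat <- beta * solve(diag(n) - (1 - beta) * W)
  dimnames(Fmat) <- dimnames(W)
  new("DiffusionOperator", genes = genes, W = W, beta = beta, Fmat = Fmat)
}

## internal: align a named heat vector to the operator's gene ordering
## (missing genes get heat 0; scored genes absent from the network are
## reported via the "nDroppedScores" attribute).
alignHeats <- function(op, heats) {
  h <- setNames(numeric(length(op@genes)), op@genes)
  shared <- intersect(names(heats), op@genes)
  h[shared] <- heats[shared]
  if (any(h < 0)) grpmError("heats must be non-negative", "invalidConfigError")
  attr(h, "nDroppedScores") <- length(setdiff(names(heats), op@genes))
  attr(h, "scored") <- shared
  h
}

## internal: permute the heat-to-gene assignment uniformly over the network
## genes (the HotNet2-style null: the same multiset of heats, randomly
## placed).
permuteHeats <- function(h) {
  setNames(sample(as.vector(h)), names(h))
}

## internal: exchanged-heat matrix restricted to positive-heat genes.
## E_ij = F_ij * h_j; a directed cycle needs an out-edge at every node and
## zero-heat genes have none, so strongly connected components live entirely
## on the positive-heat subgraph — connector nodes only shape F.
exchangedHeat <- function(op, h) {
  pos <- which(h > 0)
  E <- sweep(op@Fmat[pos, pos, drop = FALSE], 2, h[pos], "*")
  diag(E) <- 0
  E
}

## internal: strongly connected components (size >= minSize) of the
## delta-thresholded graph with edge j -> i iff E_ij > delta (strict).
sccFromE <- function(E, delta, minSize = 2) {
  idx <- which(E > delta, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  nm <- rownames(E)
  g <- igraph::graph_from_edgelist(
    cbind(nm[idx[, 2]], nm[idx[, 1]]), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  mods <- lapply(which(comp$csize >= minSize), function(k) {
    sort(names(comp$membership)[comp$membership == k])
  })
  mods[order(-vapply(mods, length, integer(1)))]
}

thresholdModules <- function(op, h, delta, minSize = 2) {
  sccFromE(exchangedHeat(op, h), delta, minSize)
}

#' Extract candidate modules at a fixed edge-removal threshold
#'
#' Computes the exchanged-heat matrix `E = F diag(heat)`, keeps directed
#' edges with `E > delta` (strict), and reports the strongly connected
#' components with at least `minSize` genes, largest first.
#'
#' @param op A [DiffusionOperator-class].
#' @param heats Named non-negative heat vector (`-log10` gene P values);
#'   network genes without a score get heat 0.
#' @param delta Non-negative edge-removal threshold.
#' @param minSize Minimum module size (default 2).
#' @return List of modules, each a list `(genes, size, delta)`, sorted by
#'   size descending; attribute `nDroppedScores` counts scored genes absent
#'   from the network.
#' @export
extractModules <- function(op, heats, delta, minSize = 2) {
  if (delta < 0) grpmError("delta must be >= 0", "invalidConfigError")
  h <- alignHeats(op, heats)
  mods <- thresholdModules(op, h, delta, minSize)
  out <- lapply(seq_along(mods), function(i) {
    list(id = sprintf("module_%02d", i), genes = mods[[i]],
         size = length(mods[[i]]), delta = delta)
  })
  attr(out, "nDroppedScores") <- attr(h, "nDroppedScores")
  out
}

#' Select edge-removal thresholds from permuted heats
#'
#' For each target size `L`, the threshold `delta_L` is the median, over
#' heat-permuted replicates, of the smallest `delta` at which the largest
#' module has at most `L` genes (found by bisection over the sorted distinct
#' exchanged-heat values). Larger targets yield smaller-or-equal thresholds.
#'
#' @param op A [DiffusionOperator-class].
#' @param heats Named heat vector.
#' @param nPerm Number of heat permutations (`>= 10`).
#' @param sizes Target largest-module sizes (default `c(5, 10, 15, 20)`).
#' @param seed Integer seed.
#' @return Named numeric vector of thresholds (names `L5`, `L10`, ...). With
#'   degenerate all-equal heats a single threshold is returned with a
#'   warning.
#' @export
selectDeltas <- function(op, heats, nPerm = 20, sizes = c(5, 10, 15, 20),
                         seed = 1L) {
  if (nPerm < 10) grpmError("need nPerm >= 10", "invalidConfigError")
  if (any(sizes < 2)) grpmError("target sizes must be >= 2 (minimum module size)",
                                "invalidConfigError")
  h <- alignHeats(op, heats)
  degenerate <- length(unique(round(h, 12))) == 1
  if (degenerate) {
    warning("all heats equal; returning a single threshold")
    sizes <- sizes[1]
  }
  set.seed(seed)
  perms <- matrix(0, length(h), nPerm)
  for (j in seq_len(nPerm)) perms[, j] <- permuteHeats(h)
  smallestDelta <- function(E, L) {
    cand <- sort(unique(E[E > 0]))
    if (!length(cand)) return(0)
    maxSize <- function(delta) {
      mods <- sccFromE(E, delta)
      if (!length(mods)) 0L else length(mods[[1]])
    }
    lo <- 0L; hi <- length(cand)      # delta = cand[i]; cand[0] means 0
    if (maxSize(0) <= L) return(0)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (maxSize(cand[mid]) <= L) hi <- mid else lo <- mid
    }
    cand[hi]
  }
  perDelta <- matrix(0, nPerm, length(sizes))
  for (j in seq_len(nPerm)) {
    E <- exchangedHeat(op, setNames(perms[, j], op@genes))
    perDelta[j, ] <- vapply(sizes, function(L) smallestDelta(E, L),
                            numeric(1))
  }
  setNames(apply(perDelta, 2, median), paste0("L", sizes))
}

#' Two-stage permutation test of module number and size
#'
#' Stage 1: for each size threshold `k` from 2 to the largest observed
#' module, the observed count `X_k` of modules with at least `k` genes is
#' compared with its null distribution under uniform permutation of the
#' heat-to-gene assignment over the network's genes: `P_k = (1 + #{perm:
#' X_k >= X_k_obs}) / (nPerm + 1)`. Stage 2 reports the smallest `k` with `P_k < alpha` and
#' the observed modules of at least that size.
#'
#' @param op A [DiffusionOperator-class].
#' @param heats Named heat vector.
#' @param delta Edge-removal threshold.
#' @param nPerm Number of permutations (default 500).
#' @param minSize Minimum module size (default 2).
#' @param alpha Stage-2 significance level (default 0.01).
#' @param seed Integer seed.
#' @return List: `modules` (observed, as in [extractModules()]),
#'   `pValues` (data.frame `k`, `observed`, `p`), `reportingK` (smallest
#'   significant `k`, or `NA`), `significant`, `significantModules`
#'   (observed modules with `size >= reportingK`).
#' @export
modulePermutationTest <- function(op, heats, delta, nPerm = 500,
                                  minSize = 2, alpha = 0.01, seed = 1L) {
  h <- alignHeats(op, heats)
  obs <- extractModules(op, heats, delta, minSize)
  obsSizes <- vapply(obs, `[[`, integer(1), "size")
  maxK <- if (length(obsSizes)) max(obsSizes) else minSize
  ks <- seq(minSize, maxK)
  obsCount <- vapply(ks, function(k) sum(obsSizes >= k), numeric(1))
  set.seed(seed)
  geCount <- numeric(length(ks))
  for (j in seq_len(nPerm)) {
    hp <- permuteHeats(h)
    permSizes <- vapply(thresholdModules(op, hp, delta, minSize), length,
                        integer(1))
    permCount <- vapply(ks, function(k) sum(permSizes >= k), numeric(1))
    geCount <- geCount + (permCount >= obsCount)
  }
  p <- permP(geCount, nPerm)
  p[obsCount == 0] <- 1   # nothing observed at this size: not significant
  sig <- which(p < alpha & obsCount > 0)
  reportingK <- if (length(sig)) ks[min(sig)] else NA_integer_
  list(
    modules = obs,
    pValues = data.frame(k = ks, observed = obsCount, p = p),
    reportingK = reportingK,
    significant = length(sig) > 0,
    significantModules = if (length(sig))
      obs[obsSizes >= reportingK] else list()
  )
}
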