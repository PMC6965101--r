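#' Simulation configuration for synthetic survival-GWAS cohorts
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' The generator emulates, at desk scale, a multi-study breast-cancer
#' survival GWAS: LD-block genotype dosages with common variants
#' (MAF > 5%), left-truncated right-censored cause-specific survival,
#' country strata with log-normal baseline multipliers, genetic principal
#' components, and estrogen-receptor subtype labels.
#'
#' @param nPatients Number of patients drawn (before prevalent-case
#'   truncation).
#' @param nStudies Number of studies; patients are assigned uniformly.
#' @param nVariants Number of variants, laid on one synthetic chromosome at
#'   `variantSpacing` bp intervals.
#' @param blockSize Variants per LD block (last block may be short).
#' @param rho Latent AR(1) within-block correlation, in `[0, 1)`.
#' @param mafRange Allele-frequency range; per-variant targets are drawn
#'   uniformly from it. Must lie within `(0, 0.5]`.
#' @param baselineHazard Cause-specific baseline hazard, events per year.
#' @param adminCensor Administrative censoring time in years (default 10).
#' @param entryMax Maximum delayed-entry (recruitment) time in years; entry
#'   is uniform on `[0, entryMax]`.
#' @param censorRate Rate of the independent competing (other-cause /
#'   loss-to-follow-up) censoring process, per year.
#' @param nStrata Number of country strata.
#' @param stratumSd SD of the log-normal per-stratum baseline multiplier.
#' @param nPcs Number of simulated principal-component covariates.
#' @param pcEffect Log-hazard effect per PC unit (default 0; PCs exist so
#'   adjustment code paths are exercised).
#' @param erPosFrac Fraction of ER-positive patients.
#' @param imputationInfo Constant imputation-quality r-squared recorded for
#'   every variant in every study.
#' @param variantSpacing Base-pair spacing between adjacent variants.
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#' @return A validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(nPatients = 200, nVariants = 50, seed = 1)
#' @export
simConfig <- function(nPatients = 3000, nStudies = 3, nVariants = 2000,
                      blockSize = 5, rho = 0.7, mafRange = c(0.1, 0.5),
                      baselineHazard = 0.05, adminCensor = 10, entryMax = 2,
                      censorRate = 0.02, nStrata = 3, stratumSd = 0.2,
                      nPcs = 2, pcEffect = 0, erPosFrac = 0.66,
                      imputationInfo = 0.99, variantSpacing = 5000,
                      seed = 1L) {
  if (nPatients < 2 || nVariants < 1) {
    grpmError("need nPatients >= 2 and nVariants >= 1", "invalidConfigError")
  }
  if (rho < 0 || rho >= 1) {
    grpmError("rho must lie in [0, 1)", "invalidConfigError")
  }
  if (length(mafRange) != 2 || any(mafRange <= 0) || any(mafRange > 0.5) ||
      mafRange[1] > mafRange[2]) {
    grpmError("mafRange must be an increasing pair within (0, 0.5]",
              "invalidConfigError")
  }
  if (blockSize < 1 || nStudies < 1 || nStrata < 1 || baselineHazard <= 0 ||
      adminCensor <= 0 || entryMax < 0 || censorRate < 0) {
    grpmError("invalid simulation parameter", "invalidConfigError")
  }
  structure(list(
    nPatients = as.integer(nPatients), nStudies = as.integer(nStudies),
    nVariants = as.integer(nVariants), blockSize = as.integer(blockSize),
    rho = rho, mafRange = mafRange, baselineHazard = baselineHazard,
    adminCensor = adminCensor, entryMax = entryMax, censorRate = censorRate,
    nStrata = as.integer(nStrata), stratumSd = stratumSd,
    nPcs = as.integer(nPcs), pcEffect = pcEffect, erPosFrac = erPosFrac,
    imputationInfo = imputationInfo, variantSpacing = variantSpacing,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

## internal: expected dosage correlation of two HWE-thresholded variants
## with shared allele frequency f and latent Gaussian correlation r.
thresholdDosageCor <- function(r, f) {
  q <- c(qnorm((1 - f)^2), qnorm((1 - f)^2 + 2 * f * (1 - f)))
  upper2 <- function(a, b) {   # P(z1 > a, z2 > b) under correlation r
    stats::integrate(function(z) {
      stats::dnorm(z) * pnorm((b - r * z) / sqrt(1 - r^2),
                              lower.tail = FALSE)
    }, a, Inf, rel.tol = 1e-9)$value
  }
  e12 <- sum(vapply(q, function(a) vapply(q, function(b) upper2(a, b),
                                          numeric(1)), numeric(2)))
  (e12 - (2 * f)^2) / (2 * f * (1 - f))
}

## internal: latent AR(1) coefficient giving a target adjacent *dosage*
## correlation rho after thresholding (inverts the attenuation numerically).
calibrateLatentRho <- function(rho, f) {
  if (rho <= 0) return(0)
  if (thresholdDosageCor(min(rho * 1.0001, 1 - 1e-9), f) >= rho) return(rho)
  stats::uniroot(function(r) thresholdDosageCor(r, f) - rho,
                 lower = rho, upper = 1 - 1e-9, tol = 1e-6)$root
}

## internal: per-variant target allele frequencies, block ids and per-block
## calibrated latent correlations — a pure function of the config seed so
## that cohort and LD reference panel share the same variant parameters.
## MAF is drawn per block (variants in strong LD share frequencies).
variantParams <- function(config) {
  set.seed(stageSeed(config$seed, "variant-params"))
  m <- config$nVariants
  nBlocks <- ceiling(m / config$blockSize)
  blockMaf <- runif(nBlocks, config$mafRange[1], config$mafRange[2])
  block <- rep(seq_len(nBlocks), each = config$blockSize)[seq_len(m)]
  latent <- vapply(blockMaf, function(f) calibrateLatentRho(config$rho, f),
                   numeric(1))
  list(maf = blockMaf[block], block = block, latent = latent)
}

#' Generate LD-structured genotype dosages
#'
#' Dosages are produced by thresholding a latent multivariate Gaussian with
#' AR(1) correlation inside each LD block (blocks independent) at the
#' Hardy-Weinberg cutpoints of each variant's target allele frequency, so
#' values are hard calls in `{0, 1, 2}` counting the effect (alt) allele.
#' The latent AR(1) coefficient is calibrated numerically so that the
#' adjacent-variant *dosage* correlation matches `rho` (thresholding would
#' otherwise attenuate it); variants within a block share their target
#' allele frequency, as LD partners do.
#'
#' @param config A [simConfig()] object.
#' @param n Number of individuals (default `config$nPatients`); use a smaller
#'   `n` with a different `sampleSeed` to draw an LD reference panel that
#'   shares the cohort's variant parameters.
#' @param sampleSeed Seed for the individual-level draw (default
#'   `config$seed`). Variant-level parameters (MAF targets, block layout)
#'   always derive from `config$seed`, so two calls with different
#'   `sampleSeed` give independent samples of the same variants.
#' @return List with `dosages` (n x nVariants matrix, dimnames set) and
#'   `variants` (data.frame: variant_id, chrom, pos, ref, alt, maf, one
#'   `info_<study>` column per study).
#' @export
generateGenotypes <- function(config, n = config$nPatients,
                              sampleSeed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  if (n < 2) grpmError("need n >= 2 individuals", "invalidConfigError")
  vp <- variantParams(config)
  m <- config$nVariants
  set.seed(stageSeed(sampleSeed, "genotypes"))
  dos <- matrix(0, n, m)
  for (b in unique(vp$block)) {
    idx <- which(vp$block == b)
    z <- matrix(rnorm(n * length(idx)), n, length(idx))
    r <- vp$latent[b]
    if (r > 0 && length(idx) > 1) {
      for (k in 2:length(idx)) {
        z[, k] <- r * z[, k - 1] + sqrt(1 - r^2) * z[, k]
      }
    }
    f <- vp$maf[idx]
    q0 <- qnorm((1 - f)^2)            # below: genotype 0
    q1 <- qnorm((1 - f)^2 + 2 * f * (1 - f))  # between: genotype 1
    dos[, idx] <- sweep(z, 2, q0, ">") + sweep(z, 2, q1, ">")
  }
  ids <- sprintf("v%05d", seq_len(m))
  dimnames(dos) <- list(sprintf("p%05d", seq_len(n)), ids)
  variants <- data.frame(
    variant_id = ids, chrom = "chr1",
    pos = config$variantSpacing * seq_len(m),
    ref = "A", alt = "G", maf = vp$maf, block = vp$block,
    stringsAsFactors = FALSE
  )
  for (s in seq_len(config$nStudies)) {
    variants[[paste0("info_study", s)]] <- config$imputationInfo
  }
  list(dosages = dos, variants = variants)
}

#' Planted ground truth for a synthetic run
#'
#' @param causalModule Character vector of gene ids forming a connected
#'   subgraph of the generated network.
#' @param causalVariants Named list mapping each module gene to its causal
#'   variant ids.
#' @param logHr Per-causal-variant log hazard ratio per dosage unit.
#' @param expressionTargets Gene ids whose expression tracks the PHS.
#' @param expressionRho Target correlation between PHS and target expression,
#'   `|rho| < 1`.
#' @param effectGroup Subtype carrying the survival effect: `"all"`,
#'   `"er_pos"` or `"er_neg"`.
#' @return A list of class `PlantedTruth`.
#' @export
plantedTruth <- function(causalModule = character(), causalVariants = list(),
                         logHr = 0.3, expressionTargets = character(),
                         expressionRho = 0.5, effectGroup = "all") {
  if (abs(expressionRho) >= 1) {
    grpmError("|expressionRho| must be < 1", "invalidConfigError")
  }
  effectGroup <- match.arg(effectGroup, c("all", "er_pos", "er_neg"))
  structure(list(causalModule = causalModule,
                 causalVariants = causalVariants, logHr = logHr,
                 expressionTargets = expressionTargets,
                 expressionRho = expressionRho, effectGroup = effectGroup),
            class = "PlantedTruth")
}

## internal: per-patient genetic linear predictor under the planted truth
truthLinearPredictor <- function(dosages, truth) {
  vs <- unlist(truth$causalVariants, use.names = FALSE)
  if (!length(vs)) return(rep(0, nrow(dosages)))
  if (!all(vs %in% colnames(dosages))) {
    grpmError("causal variants absent from dosage matrix",
              "invalidConfigError")
  }
  as.vector(dosages[, vs, drop = FALSE] %*% rep(truth$logHr, length(vs)))
}

#' Generate a left-truncated survival cohort with planted effects
#'
#' Event times are exponential with hazard
#' `baselineHazard * stratumMultiplier * exp(lp)` where `lp` sums
#' `dosage * logHr` over the planted causal variants (restricted to the
#' planted subtype when `effectGroup` is not `"all"`) plus any PC effects.
#' Entry times are uniform on `[0, entryMax]`; patients whose event or
#' censoring precedes entry are excluded (prevalent-case truncation); exit is
#' the minimum of the event time, an independent exponential competing censor
#' and administrative censoring at `adminCensor` years.
#'
#' @param dosages Patient-by-variant dosage matrix with dimnames.
#' @param truth A [plantedTruth()] object.
#' @param config A [simConfig()] object.
#' @param seed Seed for the survival draw (default derived from
#'   `config$seed`).
#' @return A [SurvivalCohort-class]; its `patient_id`s index the retained
#'   rows of `dosages`.
#' @export
generateSurvival <- function(dosages, truth, config,
                             seed = stageSeed(config$seed, "survival")) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "PlantedTruth"))
  n <- nrow(dosages)
  set.seed(seed)
  stratum <- sample(sprintf("country%02d", seq_len(config$nStrata)), n,
                    replace = TRUE)
  study <- sample(sprintf("study%d", seq_len(config$nStudies)), n,
                  replace = TRUE)
  er <- ifelse(runif(n) < config$erPosFrac, "positive", "negative")
  pcs <- matrix(rnorm(n * config$nPcs), n, config$nPcs)
  mult <- exp(rnorm(config$nStrata, 0, config$stratumSd))
  names(mult) <- sprintf("country%02d", seq_len(config$nStrata))

  lp <- truthLinearPredictor(dosages, truth)
  if (truth$effectGroup != "all") {
    want <- if (truth$effectGroup == "er_pos") "positive" else "negative"
    lp[er != want] <- 0
  }
  if (config$nPcs > 0) lp <- lp + as.vector(pcs %*%
                                             rep(config$pcEffect, config$nPcs))
  rate <- config$baselineHazard * mult[stratum] * exp(lp)
  tEvent <- rexp(n, rate)
  tCens <- if (config$censorRate > 0) rexp(n, config$censorRate) else
    rep(Inf, n)
  entry <- if (config$entryMax > 0) runif(n, 0, config$entryMax) else
    rep(0, n)
  exit <- pmin(tEvent, tCens, config$adminCensor)
  event <- as.numeric(tEvent <= pmin(tCens, config$adminCensor))
  keep <- exit > entry
  if (!any(keep)) grpmError("all patients truncated", "degenerateCohortError")
  d <- data.frame(patient_id = rownames(dosages)[keep],
                  entry = entry[keep], exit = exit[keep],
                  event = event[keep], stratum = stratum[keep],
                  study = study[keep], er_status = er[keep],
                  stringsAsFactors = FALSE)
  if (config$nPcs > 0) {
    colnames(pcs) <- sprintf("pc%d", seq_len(config$nPcs))
    d <- cbind(d, pcs[keep, , drop = FALSE])
  }
  rownames(d) <- NULL
  SurvivalCohort(d)
}

#' Generate a scale-free PPI-like network
#'
#' Preferential-attachment growth: the first node starts alone; node `k`
#' attaches `min(m, k - 1)` edges to existing nodes with probability
#' proportional to degree, so the final simple undirected graph has exactly
#' `(n - m) * m + choose(m, 2)` edges (for `n > m`).
#'
#' @param nGenes Number of nodes; names `g0001`, `g0002`, ...
#' @param m Edges attached by each incoming node (default 2).
#' @param seed Integer seed.
#' @return data.frame edge list with columns `from`, `to`.
#' @export
generateNetwork <- function(nGenes, m = 2, seed = 1L) {
  stopifnot(nGenes > m)
  set.seed(seed)
  g <- igraph::sample_pa(nGenes, power = 1, m = m, directed = FALSE,
                         algorithm = "psumtree")
  e <- igraph::as_edgelist(g, names = FALSE)
  ## decouple gene identity from attachment order: node degree must not
  ## correlate with genomic position
  ids <- sample(sprintf("g%04d", seq_len(nGenes)))
  data.frame(from = ids[e[, 1]], to = ids[e[, 2]], stringsAsFactors = FALSE)
}

#' Pick a connected module to plant in a network
#'
#' Grows a random connected subgraph inside the largest component by
#' repeatedly adding a uniformly chosen neighbour of the current set.
#' When `maxDegree` is set, growth is restricted to nodes of at most that
#' degree, emulating a pathway-like module of peripheral proteins: a module
#' centred on an extreme hub is not separable from the hub's neighbourhood
#' by any edge threshold, so hub modules make parameter-recovery studies
#' ill-posed. If the restricted snowball dead-ends it restarts (up to 50
#' attempts) before relaxing the cap.
#'
#' @param network Edge-list data.frame (`from`, `to`).
#' @param size Module size, `>= 2`.
#' @param seed Integer seed.
#' @param maxDegree Optional per-node degree cap for module members.
#' @return Character vector of `size` gene ids inducing a connected subgraph.
#' @export
plantModule <- function(network, size, seed = 1L, maxDegree = NULL) {
  stopifnot(size >= 2)
  g <- igraph::graph_from_data_frame(network, directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  nodes <- names(comp$membership)[comp$membership == big]
  if (size > length(nodes)) {
    grpmError("module size exceeds largest component", "plantingError")
  }
  deg <- igraph::degree(g)
  ok <- if (is.null(maxDegree)) nodes else nodes[deg[nodes] <= maxDegree]
  set.seed(seed)
  snowball <- function(pool) {
    for (attempt in seq_len(50)) {
      cur <- sample(pool, 1)
      while (length(cur) < size) {
        nb <- setdiff(intersect(unique(unlist(lapply(cur, function(v)
          names(igraph::neighbors(g, v))))), pool), cur)
        if (!length(nb)) break
        cur <- c(cur, sample(nb, 1))
      }
      if (length(cur) == size) return(cur)
    }
    NULL
  }
  cur <- snowball(ok)
  if (is.null(cur) && !is.null(maxDegree)) cur <- snowball(nodes)
  if (is.null(cur)) grpmError("could not grow a connected module",
                              "plantingError")
  sort(cur)
}

#' Generate expression correlated with a polygenic hazard score
#'
#' Target genes receive `rho * scale(PHS) + sqrt(1 - rho^2) * noise`
#' (times `noiseSd`); all other genes are independent noise.
#'
#' @param phs Numeric per-patient score (names used as row names).
#' @param truth A [plantedTruth()] carrying `expressionTargets` and
#'   `expressionRho`.
#' @param genes Character vector of gene ids (columns of the output).
#' @param noiseSd Marginal SD scale of expression.
#' @param seed Integer seed.
#' @return Patients-by-genes numeric matrix. If `phs` is constant the target
#'   correlation is undefined; pure noise is returned with attribute
#'   `phsConstant = TRUE` and a warning.
#' @export
generateExpression <- function(phs, truth, genes, noiseSd = 1, seed = 1L) {
  stopifnot(inherits(truth, "PlantedTruth"))
  if (abs(truth$expressionRho) >= 1) {
    grpmError("|expressionRho| must be < 1", "invalidConfigError")
  }
  n <- length(phs)
  set.seed(seed)
  expr <- matrix(rnorm(n * length(genes)), n,
                 dimnames = list(names(phs), genes))
  constant <- sd(phs) == 0 || !is.finite(sd(phs))
  targets <- intersect(truth$expressionTargets, genes)
  if (constant && length(targets) && truth$expressionRho != 0) {
    warning("PHS is constant; target correlation undefined, returning noise")
    attr(expr, "phsConstant") <- TRUE
  } else if (length(targets)) {
    z <- as.vector(scale(phs))
    r <- truth$expressionRho
    expr[, targets] <- r * z + sqrt(1 - r^2) * expr[, targets]
  }
  expr * noiseSd
}

#' Generate gene sets (one planted, the rest random)
#'
#' @param genes Universe of gene ids.
#' @param targets Planted set members (emitted as set `"planted_targets"`).
#' @param nSets Number of additional random sets.
#' @param sizeRange Size range of the random sets.
#' @param seed Integer seed.
#' @return Named list of character vectors (GMT-style gene sets).
#' @export
generateGeneSets <- function(genes, targets, nSets = 20,
                             sizeRange = c(15, 50), seed = 1L) {
  set.seed(seed)
  sets <- lapply(seq_len(nSets), function(i) {
    sample(genes, sample(seq(sizeRange[1], min(sizeRange[2], length(genes))),
                         1))
  })
  names(sets) <- sprintf("random_set_%02d", seq_len(nSets))
  c(list(planted_targets = targets), sets)
}

#' Tile a synthetic chromosome with gene regions
#'
#' Genes are placed at a regular period spanning the simulated variant range
#' so that 50-kb gene windows overlap a realistic handful of variants and
#' neighbouring genes share flanking variants.
#'
#' @param config A [simConfig()] object (fixes the chromosome span).
#' @param nGenes Number of genes.
#' @param geneLength Gene length in bp.
#' @return data.frame: `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
generateAnnotation <- function(config, nGenes, geneLength = 20000) {
  span <- config$nVariants * config$variantSpacing
  period <- max(geneLength, floor(span / nGenes))
  start <- (seq_len(nGenes) - 1) * period + 1
  data.frame(gene = sprintf("g%04d", seq_len(nGenes)), chrom = "chr1",
             start = start, end = start + geneLength - 1,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic GRPM study
#'
#' Convenience wrapper producing every input the pipeline consumes: cohort
#' genotypes, an independent LD reference panel, a gene annotation, a
#' scale-free protein network with a planted connected module, causal
#' variants (one per module gene, near the gene midpoint), a left-truncated
#' survival cohort, gene sets, and expression correlated with the planted
#' genetic score.
#'
#' The protein network is larger than the scored gene set, as real
#' interactomes are: `nGenes` annotated genes are placed on randomly chosen
#' network nodes (the planted module on a connected node set) and the
#' remaining nodes are unscored connector proteins that only mediate
#' diffusion.
#'
#' @param config A [simConfig()] object.
#' @param nGenes Number of annotated (scored) genes.
#' @param nNetworkNodes Total protein-network nodes (`>= nGenes`).
#' @param networkM Preferential-attachment edges per incoming node for the
#'   protein network (default 1: a tree-like high-confidence backbone, which
#'   keeps the separation between module-internal and background coupling at
#'   desk scale; see the methods vignette).
#' @param moduleSize Planted module size; `0` plants nothing (null run).
#' @param moduleMaxDegree Degree cap for planted module members (see
#'   [plantModule()]).
#' @param logHr Per-causal-variant log hazard ratio.
#' @param effectGroup Subtype carrying the effect (see [plantedTruth()]).
#' @param expressionRho Target PHS-expression correlation.
#' @param nPanel LD reference panel size.
#' @param nExpressionTargets Number of expression target genes.
#' @return List: `dosages`, `variants`, `panel`, `annotation`, `network`,
#'   `truth`, `cohort`, `geneSets`, `expression`.
#' @export
simulateGrpmData <- function(config, nGenes = 120, nNetworkNodes = 2000,
                             networkM = 1, moduleSize = 6,
                             moduleMaxDegree = 8,
                             logHr = 0.3, effectGroup = "all",
                             expressionRho = 0.5, nPanel = 500,
                             nExpressionTargets = 40) {
  stopifnot(nNetworkNodes >= nGenes)
  geno <- generateGenotypes(config)
  panel <- generateGenotypes(config, n = nPanel,
                             sampleSeed = stageSeed(config$seed, "panel"))
  annotation <- generateAnnotation(config, nGenes)
  rawNet <- generateNetwork(nNetworkNodes, m = networkM,
                            seed = stageSeed(config$seed, "network"))
  nodes <- sort(unique(c(rawNet$from, rawNet$to)))
  moduleNodes <- if (moduleSize >= 2) {
    plantModule(rawNet, moduleSize, seed = stageSeed(config$seed, "plant"),
                maxDegree = moduleMaxDegree)
  } else character()
  ## assign gene identities: planted genes on the connected node set, the
  ## rest scattered; remaining nodes become unscored connector proteins
  set.seed(stageSeed(config$seed, "gene-placement"))
  geneNodes <- c(moduleNodes,
                 sample(setdiff(nodes, moduleNodes),
                        nGenes - length(moduleNodes)))
  nodeName <- setNames(sprintf("prot%05d", seq_along(nodes)), nodes)
  nodeName[geneNodes] <- sample(annotation$gene)
  network <- data.frame(from = unname(nodeName[rawNet$from]),
                        to = unname(nodeName[rawNet$to]),
                        stringsAsFactors = FALSE)
  if (moduleSize >= 2) {
    module <- sort(unname(nodeName[moduleNodes]))
    causal <- lapply(setNames(module, module), function(g) {
      reg <- annotation[annotation$gene == g, ]
      ## the variant closest to the gene midpoint (falling back to the
      ## nearest variant overall when the body holds none)
      mid <- (reg$start + reg$end) / 2
      inBody <- which(geno$variants$pos >= reg$start &
                        geno$variants$pos <= reg$end)
      if (!length(inBody)) inBody <- seq_len(nrow(geno$variants))
      geno$variants$variant_id[
        inBody[which.min(abs(geno$variants$pos[inBody] - mid))]]
    })
  } else {
    module <- character()
    causal <- list()
  }
  set.seed(stageSeed(config$seed, "targets"))
  targets <- sample(annotation$gene, nExpressionTargets)
  truth <- plantedTruth(causalModule = module, causalVariants = causal,
                        logHr = logHr, expressionTargets = targets,
                        expressionRho = expressionRho,
                        effectGroup = effectGroup)
  cohort <- generateSurvival(geno$dosages, truth, config)
  geneticScore <- truthLinearPredictor(geno$dosages, truth)
  names(geneticScore) <- rownames(geno$dosages)
  geneticScore <- geneticScore[patientIds(cohort)]
  expr <- generateExpression(geneticScore, truth, annotation$gene,
                             seed = stageSeed(config$seed, "expression"))
  geneSets <- generateGeneSets(annotation$gene, targets,
                               seed = stageSeed(config$seed, "genesets"))
  list(dosages = geno$dosages, variants = geno$variants,
       panel = panel$dosages, annotation = annotation, network = network,
       truth = truth, cohort = cohort, geneSets = geneSets,
       expression = expr)
}
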