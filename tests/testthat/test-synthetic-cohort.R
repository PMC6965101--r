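test_that("genotype generator hits MAF targets and block LD structure", {
  cfg <- simConfig(nPatients = 5000, nVariants = 60, blockSize = 10,
                   rho = 0.9, mafRange = c(0.1, 0.5), seed = 3)
  g <- generateGenotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  expect_lt(max(abs(colMeans(g$dosages) / 2 - g$variants$maf)), 0.05)
  adj <- which(g$variants$block[-60] == g$variants$block[-1])
  cc <- vapply(adj, function(k) cor(g$dosages[, k], g$dosages[, k + 1]),
               numeric(1))
  expect_true(all(cc > 0.8 & cc <= 1))         # calibrated to rho +- 0.1
  crossPairs <- which(g$variants$block[-60] != g$variants$block[-1])
  cx <- vapply(crossPairs, function(k) cor(g$dosages[, k], g$dosages[, k + 1]),
               numeric(1))
  expect_lt(mean(abs(cx)), 0.05)

  cfg0 <- simConfig(nPatients = 5000, nVariants = 20, blockSize = 10,
                    rho = 0, seed = 5)
  g0 <- generateGenotypes(cfg0)
  x <- abs(cor(g0$dosages)); diag(x) <- NA
  expect_lt(mean(x, na.rm = TRUE), 0.05)       # independence case

  expect_identical(generateGenotypes(cfg)$dosages, g$dosages)  # same seed
  pan <- generateGenotypes(cfg, n = 300, sampleSeed = 99)
  expect_false(identical(pan$dosages[1:300, ], g$dosages[1:300, ]))
  expect_identical(pan$variants$maf, g$variants$maf)  # shared variant params
})

test_that("invalid simulation configs are rejected", {
  expect_error(simConfig(nPatients = 1), class = "invalidConfigError")
  expect_error(simConfig(nVariants = 0), class = "invalidConfigError")
  expect_error(simConfig(rho = 1), class = "invalidConfigError")
  expect_error(simConfig(mafRange = c(0.1, 0.6)),
               class = "invalidConfigError")
  expect_error(plantedTruth(expressionRho = 1),
               class = "invalidConfigError")
})

test_that("survival generator matches the exponential event fraction", {
  # entryMax 0, no competing censor: P(event by 10y) = 1 - exp(-0.05 * 10)
  cfg <- simConfig(nPatients = 4000, nVariants = 4, baselineHazard = 0.05,
                   entryMax = 0, censorRate = 0, stratumSd = 0, seed = 8)
  g <- generateGenotypes(cfg)
  coh <- generateSurvival(g$dosages, plantedTruth(), cfg)
  expect_equal(length(coh), 4000)              # no truncation at entryMax 0
  d <- cohortData(coh)
  expect_true(all(d$entry < d$exit))
  expect_true(all(d$event %in% c(0, 1)))
  expect_true(all(d$exit <= 10 + 1e-12))
  expect_equal(mean(d$event), 1 - exp(-0.5), tolerance = 0.05)
})

test_that("prevalent cases are excluded under delayed entry", {
  cfg <- simConfig(nPatients = 2000, nVariants = 4, entryMax = 3,
                   baselineHazard = 0.2, censorRate = 0, seed = 9)
  g <- generateGenotypes(cfg)
  coh <- generateSurvival(g$dosages, plantedTruth(), cfg)
  expect_lt(length(coh), 2000)                 # some truncation happened
  expect_true(all(cohortData(coh)$entry < cohortData(coh)$exit))
})

test_that("a planted per-variant effect is recoverable by Cox regression", {
  hits <- 0
  for (seed in 1:5) {
    cfg <- simConfig(nPatients = 5000, nVariants = 2, rho = 0,
                     entryMax = 1, seed = 100 + seed)
    g <- generateGenotypes(cfg)
    truth <- plantedTruth(causalModule = "g1",
                          causalVariants = list(g1 = "v00001"),
                          logHr = 0.3)
    coh <- generateSurvival(g$dosages, truth, cfg)
    fe <- fitVariantCox(coh, g$dosages[patientIds(coh), "v00001"])
    hits <- hits + (abs(fe$beta - 0.3) <= 2 * fe$se)
  }
  expect_gte(hits, 4)
})

test_that("network generator yields the exact preferential-attachment edge count", {
  net <- generateNetwork(200, m = 2, seed = 1)
  expect_equal(nrow(net), 198 * 2 + 1)
  g <- igraph::graph_from_data_frame(net, directed = FALSE)
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))
  expect_identical(generateNetwork(200, m = 2, seed = 1), net)
  expect_false(identical(generateNetwork(200, m = 2, seed = 2), net))
})

test_that("planted modules induce connected subgraphs", {
  net <- generateNetwork(100, m = 2, seed = 4)
  mod <- plantModule(net, 4, seed = 2)
  expect_length(mod, 4)
  g <- igraph::graph_from_data_frame(net, directed = FALSE)
  sub <- igraph::induced_subgraph(g, mod)
  expect_true(igraph::is_connected(sub))
  expect_gte(igraph::ecount(sub), 3)
  expect_error(plantModule(net, 101, seed = 1), class = "plantingError")
})

test_that("expression generator plants the requested PHS correlation", {
  genes <- sprintf("g%04d", 1:100)
  phs <- rnorm(440); names(phs) <- paste0("p", 1:440)
  for (seed in 1:3) {
    truth <- plantedTruth(expressionTargets = genes[1:20],
                          expressionRho = 0.5)
    e <- generateExpression(phs, truth, genes, seed = seed)
    rt <- cor(phs, e[, 1:20])
    expect_true(all(rt > 0.4 & rt < 0.6))
    rn <- cor(phs, e[, 21:100])
    expect_lt(max(abs(rn)), 0.2)
  }
  # rho = 0: everything is noise
  e0 <- generateExpression(phs, plantedTruth(expressionTargets = genes[1:20],
                                             expressionRho = 0),
                           genes, seed = 1)
  expect_lt(max(abs(cor(phs, e0))), 0.15)
  # constant PHS: flagged, not an error
  expect_warning(
    ec <- generateExpression(rep(1, 440),
                             plantedTruth(expressionTargets = genes[1:5],
                                          expressionRho = 0.5),
                             genes, seed = 1),
    "constant")
  expect_true(isTRUE(attr(ec, "phsConstant")))
})
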