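test_that("variants map to gene windows with inclusive boundaries", {
  ann <- data.frame(gene = c("gA", "gB", "gC"), chrom = "chr1",
                    start = c(110000, 200000, 230000),
                    end = c(120000, 210000, 240000))
  v <- data.frame(variant_id = c("v1", "v2", "v3", "v4"), chrom = "chr1",
                  pos = c(60000, 59999, 215000, 500000))
  regions <- mapVariantsToGenes(ann, v, window = 50000)
  expect_true("v1" %in% regions$gA$variants)    # exactly start - 50000
  expect_false("v2" %in% regions$gA$variants)   # one bp outside
  # v3 sits between gB and gC (30 kb apart): member of both
  expect_true("v3" %in% regions$gB$variants)
  expect_true("v3" %in% regions$gC$variants)
  # v4 falls in no window and gC has exactly one member
  expect_identical(regions$gC$variants, "v3")
})

test_that("HLA genes and variant-free genes are dropped", {
  ann <- data.frame(gene = c("inHla", "normal", "empty"),
                    chrom = c("chr6", "chr1", "chr1"),
                    start = c(29000000, 100000, 5e6),
                    end = c(29010000, 110000, 5e6 + 1e4))
  v <- data.frame(variant_id = c("v1", "v2"), chrom = c("chr6", "chr1"),
                  pos = c(29005000, 105000))
  regions <- mapVariantsToGenes(ann, v)
  expect_named(regions, "normal")
  expect_equal(attr(regions, "nHlaExcluded"), 1L)
  regionsKeep <- mapVariantsToGenes(ann, v, excludeHla = FALSE)
  expect_setequal(names(regionsKeep), c("inHla", "normal"))
})

test_that("max-chi-squared gene P matches closed forms", {
  # single variant: identity
  s1 <- genePMaxChisq(0.01, gene = "g", seed = 1)
  expect_equal(s1$p, 0.01)
  expect_equal(s1$heat, 2)

  # independent variants: P = 1 - (1 - p_top)^m
  s2 <- genePMaxChisq(c(0.05, 0.5), diag(2), mcMin = 1e5, seed = 2)
  exp2 <- 1 - (1 - 0.05)^2
  expect_lt(abs(s2$p - exp2), 3 * mcSe(exp2, s2$mc_draws))

  ps3 <- c(0.2, 0.1, 0.6)
  s3 <- genePMaxChisq(ps3, diag(3), mcMin = 1e5, seed = 3)
  exp3 <- 1 - (1 - 0.1)^3
  expect_lt(abs(s3$p - exp3), 3 * mcSe(exp3, s3$mc_draws))

  # perfectly correlated duplicate: invariant
  ld <- matrix(1, 2, 2)
  s4 <- genePMaxChisq(c(0.01, 0.01), ld, mcMin = 1e5, seed = 4)
  expect_lt(abs(s4$p - 0.01), 3 * mcSe(0.01, s4$mc_draws))
})

test_that("sum-chi-squared gene P matches the weighted chi-squared null", {
  expect_equal(genePSumChisq(0.04, gene = "g", seed = 1)$p, 0.04)

  # independent variants: null is chi-squared with m df
  m <- 4
  ps <- rep(0.5, m)
  s <- genePSumChisq(ps, diag(m), mcMin = 1e5, seed = 2)
  T <- m * qchisq(0.5, 1, lower.tail = FALSE)
  exact <- pchisq(T, df = m, lower.tail = FALSE)
  expect_lt(abs(s$p - exact), 3 * mcSe(exact, s$mc_draws))

  # rank-1 LD (all-ones): null collapses to m * chisq_1
  ld1 <- matrix(1, 3, 3)
  ps1 <- c(0.1, 0.2, 0.3)
  s1 <- genePSumChisq(ps1, ld1, mcMin = 1e5, seed = 3)
  T1 <- sum(qchisq(ps1, 1, lower.tail = FALSE))
  exact1 <- pchisq(T1 / 3, df = 1, lower.tail = FALSE)
  expect_lt(abs(s1$p - exact1), 3 * mcSe(exact1, s1$mc_draws))
})

test_that("gene P values are reproducible and respect the floor", {
  ld <- diag(3)
  a <- genePMaxChisq(c(1e-10, 0.5, 0.5), ld, mcMin = 1e4, mcCap = 1e5,
                     seed = 7)
  b <- genePMaxChisq(c(1e-10, 0.5, 0.5), ld, mcMin = 1e4, mcCap = 1e5,
                     seed = 7)
  expect_identical(a$p, b$p)
  # cap reached without exceedances: the union-bound tail extension applies
  expect_equal(a$p, 3 * 1e-10)
  expect_gt(a$p, 0)
  # without an extreme variant the floor applies as usual
  fl <- genePMaxChisq(c(1e-3, 0.5), diag(2), mcMin = 1e3, mcCap = 1e3,
                      seed = 8)
  expect_gte(fl$p, 1 / (1e3 + 1))
  expect_error(genePMaxChisq(numeric(0), diag(0)),
               class = "emptyGeneError")
  expect_error(genePMaxChisq(c(0.5, 0.5), matrix(c(1, 2, 0, 1), 2)),
               class = "schemaError")
})

test_that("lowering a variant P never raises the max-statistic gene P", {
  set.seed(11)
  for (i in 1:5) {
    m <- sample(2:4, 1)
    ps <- runif(m, 0.05, 0.9)
    ld <- diag(m)
    base <- genePMaxChisq(ps, ld, mcMin = 1e5, seed = 20 + i)
    ps2 <- ps
    j <- sample(m, 1)
    ps2[j] <- ps2[j] / 10
    better <- genePMaxChisq(ps2, ld, mcMin = 1e5, seed = 20 + i)
    tol <- 3 * (mcSe(base$p, base$mc_draws) + mcSe(better$p,
                                                   better$mc_draws))
    expect_lte(better$p, base$p + tol)
  }
})

test_that("statistic comparison reports calibrated genomic inflation", {
  set.seed(22)
  pu <- runif(2000)
  dfU <- data.frame(gene = paste0("g", 1:2000), p = pu)
  dfH <- data.frame(gene = paste0("g", 1:2000), p = pu / 2)
  cmp <- chooseStatistic(dfU, dfU)
  expect_gt(cmp$lambda[["max"]], 0.9)
  expect_lt(cmp$lambda[["max"]], 1.1)
  expect_identical(cmp$qq$max, cmp$qq$sum)
  cmp2 <- chooseStatistic(dfH, dfU)
  expect_gt(cmp2$lambda[["max"]], 1)
  expect_identical(cmp2$recommended, "max")
})

test_that("degree bias diagnostic is exact on identity and null on noise", {
  net <- generateNetwork(500, m = 2, seed = 3)
  g <- igraph::graph_from_data_frame(net, directed = FALSE)
  deg <- igraph::degree(g)
  sc <- data.frame(gene = names(deg), heat = as.numeric(deg))
  expect_equal(degreeBiasCheck(sc, net)$r, 1, tolerance = 1e-12)
  set.seed(5)
  scNull <- data.frame(gene = names(deg), heat = runif(500))
  expect_lt(abs(degreeBiasCheck(scNull, net)$r), 0.1)
  expect_error(degreeBiasCheck(sc[1:2, ], net), class = "schemaError")
})

test_that("panel LD estimation matches direct dosage correlation", {
  cfg <- simConfig(nPatients = 400, nVariants = 10, blockSize = 5,
                   rho = 0.8, seed = 31)
  g <- generateGenotypes(cfg)
  ld <- panelLdMatrix(g$dosages, c("v00001", "v00002", "v00006"))
  expect_equal(ld[1, 2], cor(g$dosages[, 1], g$dosages[, 2]))
  expect_equal(diag(ld), c(v00001 = 1, v00002 = 1, v00006 = 1))
  expect_error(panelLdMatrix(g$dosages, "nope"), class = "schemaError")
})
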