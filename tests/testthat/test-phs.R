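# Shared fixture: a small cohort with one strong planted variant among
# null LD-structured candidates.
phsFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simConfig(nPatients = 2000, nVariants = 30, blockSize = 5,
                       rho = 0.5, entryMax = 1, seed = 202)
      g <- generateGenotypes(cfg)
      truth <- plantedTruth(causalModule = "g1",
                            causalVariants = list(g1 = "v00011"),
                            logHr = 0.5)
      coh <- generateSurvival(g$dosages, truth, cfg)
      cache <<- list(cfg = cfg, g = g, coh = coh,
                     dos = g$dosages[patientIds(coh), ])
    }
    cache
  }
})

test_that("module variant pools are deduplicated unions over gene windows", {
  ann <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                    start = c(100000, 160000), end = c(120000, 180000))
  v <- data.frame(variant_id = c("shared", "onlyA", "onlyB"),
                  chrom = "chr1", pos = c(140000, 60000, 220000))
  regions <- mapVariantsToGenes(ann, v, window = 50000)
  pool <- moduleVariantPool(c("gA", "gB"), regions)
  expect_setequal(pool, c("shared", "onlyA", "onlyB"))
  expect_equal(sum(pool == "shared"), 1)       # appears once
  expect_warning(p2 <- moduleVariantPool(c("gA", "missing"), regions),
                 "absent")
  expect_setequal(p2, c("shared", "onlyA"))
  expect_identical(moduleVariantPool("gA", regions,
                                     keepVariants = "onlyA"), "onlyA")
})

test_that("lasso selection finds a strong planted variant among nulls", {
  fx <- phsFixture()
  sel <- lassoCoxSelect(fx$dos, fx$coh, nfolds = 10, seed = 1)
  expect_true("v00011" %in% sel ||
                any(panelLdMatrix(fx$dos, c(sel, "v00011"))[, "v00011"]^2
                    > 0.8))   # a perfect-LD proxy counts as recovery
})

test_that("lasso on pure-noise candidates usually selects nothing", {
  cfg <- simConfig(nPatients = 800, nVariants = 20, rho = 0,
                   entryMax = 1, seed = 301)
  g <- generateGenotypes(cfg)
  coh <- generateSurvival(g$dosages, plantedTruth(), cfg)
  empties <- 0
  for (s in 4:8) {
    cfg <- simConfig(nPatients = 800, nVariants = 20, rho = 0,
                     entryMax = 1, seed = 300 + s)
    g <- generateGenotypes(cfg)
    coh <- generateSurvival(g$dosages, plantedTruth(), cfg)
    sel <- lassoCoxSelect(g$dosages[patientIds(coh), ], coh, seed = s)
    empties <- empties + (length(sel) == 0)
  }
  expect_gte(empties, 3)
})

test_that("refit produces exact linear-predictor scores (Eq. 1)", {
  fx <- phsFixture()
  sel <- c("v00011", "v00001", "v00020")
  rs <- refitAndScore(sel, fx$coh, fx$dos, fx$g$variants, moduleId = "m1")
  expect_s4_class(rs$model, "PHSModel")
  manual <- as.vector(fx$dos[, phsVariants(rs$model), drop = FALSE] %*%
                        rs$model@beta)
  expect_lt(max(abs(rs$scores - manual)), 1e-12)
  # permuting the variant order leaves the scores unchanged
  rs2 <- refitAndScore(rev(sel), fx$coh, fx$dos, fx$g$variants,
                       moduleId = "m1")
  expect_equal(unname(sort(rs2$scores)), unname(sort(rs$scores)),
               tolerance = 1e-10)
  expect_equal(rs$model@trainMean, mean(rs$scores))
  expect_equal(rs$model@trainSd, sd(rs$scores))
  expect_error(refitAndScore(character(), fx$coh, fx$dos, fx$g$variants),
               class = "emptySelectionError")
})

test_that("a duplicated causal column is handled by collinearity dropping", {
  fx <- phsFixture()
  dos2 <- cbind(fx$dos, vdup = fx$dos[, "v00011"])
  vars2 <- rbind(fx$g$variants[, c("variant_id", "chrom", "pos", "ref",
                                   "alt", "maf")],
                 data.frame(variant_id = "vdup", chrom = "chr1", pos = 1,
                            ref = "A", alt = "G", maf = 0.3))
  expect_warning(
    rs <- refitAndScore(c("v00011", "vdup"), fx$coh, dos2, vars2,
                        moduleId = "m"),
    "collinear")
  expect_length(phsVariants(rs$model), 1)
})

test_that("a hand-built model scores by the exact dot product", {
  model <- new("PHSModel", moduleId = "toy", variants = c("v1", "v2"),
               effectAllele = c("G", "G"), otherAllele = c("A", "A"),
               beta = c(0.3, -0.1), trainMaf = c(0.25, 0.4),
               trainMean = 0, trainSd = 1, group = "all")
  dos <- matrix(c(2, 0, 1, 1), 2, 2,
                dimnames = list(c("p1", "p2"), c("v1", "v2")))
  sc <- applyPHS(model, dos)
  expect_equal(unname(sc), c(0.3 * 2 - 0.1 * 1, 0.3 * 0 - 0.1 * 1))
})

test_that("PHS transfer is idempotent, flip-invariant and impute-aware", {
  fx <- phsFixture()
  rs <- refitAndScore(c("v00011", "v00002"), fx$coh, fx$dos,
                      fx$g$variants, moduleId = "m1")
  model <- rs$model
  # idempotence on training data
  expect_equal(applyPHS(model, fx$dos)[names(rs$scores)], rs$scores,
               tolerance = 1e-12)
  # allele flip: reflected dosages with swapped allele labels give the
  # same scores
  vflip <- fx$g$variants
  i <- vflip$variant_id %in% phsVariants(model)
  tmp <- vflip$ref[i]; vflip$ref[i] <- vflip$alt[i]; vflip$alt[i] <- tmp
  dosFlip <- fx$dos
  dosFlip[, phsVariants(model)] <- 2 - dosFlip[, phsVariants(model)]
  expect_equal(applyPHS(model, dosFlip, vflip), applyPHS(model, fx$dos),
               tolerance = 1e-12)
  # missing variant: error unless imputation is enabled
  dosMiss <- fx$dos[, setdiff(colnames(fx$dos), "v00002")]
  expect_error(applyPHS(model, dosMiss), class = "missingVariantError")
  expect_message(scImp <- applyPHS(model, dosMiss, imputeMissing = TRUE),
                 "imputing")
  i2 <- which(phsVariants(model) == "v00002")
  manual <- model@beta[-i2] * fx$dos[, phsVariants(model)[-i2]] +
    model@beta[i2] * 2 * model@trainMaf[i2]
  expect_equal(unname(scImp), unname(manual), tolerance = 1e-12)
})

test_that("overlapping candidate pools give strongly correlated PHSs", {
  # two modules sharing the causal region: their scores must agree
  fx <- phsFixture()
  rsA <- refitAndScore(c("v00011", "v00001"), fx$coh, fx$dos,
                       fx$g$variants, moduleId = "A")
  rsB <- refitAndScore(c("v00011", "v00025"), fx$coh, fx$dos,
                       fx$g$variants, moduleId = "B")
  expect_gt(cor(rsA$scores, rsB$scores), 0.9)
})

test_that("cross-validation folds always contain events", {
  ev <- c(rep(1, 12), rep(0, 88))
  f <- grpmnet:::cvFolds(ev, 10, seed = 1)
  expect_true(all(tabulate(f[ev == 1], 10) > 0))
  expect_error(grpmnet:::cvFolds(c(1, rep(0, 50)), 10, seed = 1),
               class = "foldConstructionError")
})
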