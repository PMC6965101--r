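test_that("the Cox fit matches a brute-force partial-likelihood maximiser", {
  toy <- toyCohort()
  d <- cohortData(toy$cohort)
  fe <- fitVariantCox(toy$cohort, toy$dosage, covariates = character())
  ref <- coxGridOracle(d$entry, d$exit, d$event, toy$dosage)
  expect_lt(abs(fe$beta - ref), 2e-4)

  # with two strata and delayed entry
  d2 <- d; d2$stratum <- rep(c("c1", "c2"), 3)
  coh2 <- SurvivalCohort(d2)
  fe2 <- fitVariantCox(coh2, toy$dosage, covariates = character())
  ref2 <- coxGridOracle(d2$entry, d2$exit, d2$event, toy$dosage, d2$stratum)
  expect_lt(abs(fe2$beta - ref2), 2e-4)
})

test_that("p = 2*pnorm(-|beta/se|) and degenerate inputs error", {
  toy <- toyCohort()
  fe <- fitVariantCox(toy$cohort, toy$dosage, covariates = character())
  expect_equal(fe$p, 2 * pnorm(-abs(fe$beta / fe$se)), tolerance = 1e-10)
  expect_error(fitVariantCox(toy$cohort, rep(1, 6)),
               class = "monomorphicVariantError")
  d <- cohortData(toy$cohort); d$event <- 0
  expect_error(fitVariantCox(SurvivalCohort(d), toy$dosage),
               class = "noInformationError")
})

test_that("delayed-entry fit with all entries 0 equals the standard Cox fit", {
  set.seed(42)
  n <- 200
  d <- data.frame(patient_id = paste0("p", 1:n), entry = 0,
                  exit = round(rexp(n, 0.2) + 0.1, 3),
                  event = rbinom(n, 1, 0.6), stratum = "c1", study = "s1",
                  er_status = "positive")
  x <- rbinom(n, 2, 0.3)
  fe <- fitVariantCox(SurvivalCohort(d), x, covariates = character())
  std <- survival::coxph(survival::Surv(d$exit, d$event) ~ x,
                         ties = "breslow")
  expect_equal(fe$beta, unname(coef(std)), tolerance = 1e-8)
})

test_that("single-stratum stratified fit equals the unstratified fit", {
  toy <- toyCohort()
  a <- fitVariantCox(toy$cohort, toy$dosage, covariates = character(),
                     useStrata = TRUE)
  b <- fitVariantCox(toy$cohort, toy$dosage, covariates = character(),
                     useStrata = FALSE)
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("null variants give uniform two-sided P values", {
  cfg <- simConfig(nPatients = 500, nVariants = 2000, rho = 0,
                   entryMax = 1, seed = 77)
  g <- generateGenotypes(cfg)
  coh <- generateSurvival(g$dosages, plantedTruth(), cfg)
  dos <- g$dosages[patientIds(coh), ]
  ps <- vapply(seq_len(2000), function(j) {
    fitVariantCox(coh, dos[, j], covariates = character())$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_gte(mean(ps < 0.05), 0.04)
  expect_lte(mean(ps < 0.05), 0.06)
})

test_that("fixed-effects meta-analysis combines by inverse variance", {
  one <- data.frame(variant_id = "v", beta = 0.2, se = 0.1, n = 10,
                    n_events = 5)
  m1 <- metaFixedEffects(one)
  expect_equal(m1$beta, 0.2)
  expect_equal(m1$se, 0.1)

  two <- rbind(one, one)
  m2 <- metaFixedEffects(two)
  expect_equal(m2$beta, 0.2)
  expect_equal(m2$se, 0.1 / sqrt(2))

  mix <- data.frame(variant_id = "v", beta = c(0.2, 0), se = c(0.1, 0.2),
                    n = c(10, 10), n_events = c(5, 5))
  m3 <- metaFixedEffects(mix)   # weights 100 and 25
  expect_equal(m3$beta, 0.16)
  expect_equal(m3$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(m3$p, 2 * pnorm(-abs(m3$beta / m3$se)))
  expect_error(metaFixedEffects(NULL), class = "emptyMetaError")

  # property: combined SE never exceeds the best single study
  set.seed(1)
  for (i in 1:10) {
    est <- data.frame(variant_id = "v", beta = rnorm(3),
                      se = runif(3, 0.05, 0.5), n = 1, n_events = 1)
    expect_lte(metaFixedEffects(est)$se, min(est$se))
  }
})

test_that("variant filtering applies strict MAF and per-study info rules", {
  v <- data.frame(variant_id = c("a", "b", "c", "d"),
                  maf = c(0.04, 0.3, 0.5, 0.2),
                  info_study1 = c(0.99, 0.6, 0.8, 0.95),
                  info_study2 = c(0.99, 0.85, 0.8, 0.7))
  flt <- filterVariants(v)
  expect_identical(flt$keep, c("b", "d"))        # a: MAF, c: info == 0.8
  expect_identical(flt$usableStudies$b, "study2") # meta uses study2 only
  expect_identical(flt$usableStudies$d, "study1")
  expect_error(filterVariants(v[, 1:2]), class = "schemaError")
})

test_that("per-study GWAS with meta-analysis recovers a planted effect", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- simConfig(nPatients = 5000, nVariants = 2, nStudies = 2,
                     rho = 0, mafRange = c(0.3, 0.3), entryMax = 1,
                     seed = 500 + seed)
    g <- generateGenotypes(cfg)
    truth <- plantedTruth(causalModule = "g1",
                          causalVariants = list(g1 = "v00001"), logHr = 0.3)
    coh <- generateSurvival(g$dosages, truth, cfg)
    summ <- runSurvivalGwas(coh, g$dosages, g$variants)
    row <- summ[summ$variant_id == "v00001", ]
    hits <- hits + (abs(row$beta - 0.3) <= 2 * row$se)
  }
  expect_gte(hits, 17)   # ~95% nominal coverage of beta +- 2 SE
})
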