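grpmConfigDefaults <- function() {
  list(
    sim = list(nPatients = 3000, nStudies = 3, nVariants = 2000,
               blockSize = 5, rho = 0.7, mafRange = c(0.1, 0.5),
               baselineHazard = 0.05, adminCensor = 10, entryMax = 2,
               censorRate = 0.02, nStrata = 3, stratumSd = 0.2, nPcs = 2,
               pcEffect = 0, erPosFrac = 0.66, imputationInfo = 0.99,
               variantSpacing = 5000),
    nGenes = 120, nNetworkNodes = 2000, networkM = 1, moduleSize = 6,
    moduleMaxDegree = 8, logHr = 0.3,
    effectGroup = "all",
    expressionRho = 0.5, nPanel = 500,
    group = "all",
    gwas = list(mafMin = 0.05, infoMin = 0.8),
    geneScores = list(window = 50000, stat = "max", mcMin = 1e4,
                      mcCap = 1e5, excludeHla = TRUE),
    propagation = list(beta = 0.4, nPermDelta = 20,
                       deltaSizes = c(2, 3), nPerm = 500,
                       alpha = 0.01),
    phs = list(nfolds = 10, selectionStudy = NA),
    validation = list(alpha = 0.05, nPcs = 2),
    downstream = list(enabled = TRUE, weight = 1, nPerm = 1000,
                      minSize = 15, maxSize = 500, pMax = 0.001,
                      fdrMax = 0.05),
    holdoutStudy = NA
  )
}

#' Build and validate a pipeline run configuration
#'
#' Merges user overrides into the defaults, rejecting unknown keys at both
#' levels. The configuration round-trips losslessly through JSON
#' ([writeGrpmConfig()] / [readGrpmConfig()]).
#'
#' @param overrides Named list (possibly nested) of settings to change.
#' @return A validated list of class `GrpmConfig`.
#' @examples
#' cfg <- grpmConfig(list(sim = list(nPatients = 500), moduleSize = 4))
#' @export
grpmConfig <- function(overrides = list()) {
  defaults <- grpmConfigDefaults()
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    grpmError(paste("unknown config keys:", paste(bad, collapse = ", ")),
              "invalidConfigError")
  }
  for (key in names(overrides)) {
    if (is.null(overrides[[key]])) next   # JSON null: leave the default
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      sub <- overrides[[key]]
      sub <- sub[!vapply(sub, is.null, logical(1))]
      badSub <- setdiff(names(sub), names(defaults[[key]]))
      if (length(badSub)) {
        grpmError(paste0("unknown config keys under '", key, "': ",
                         paste(badSub, collapse = ", ")),
                  "invalidConfigError")
      }
      defaults[[key]] <- modifyList(defaults[[key]], sub)
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  structure(defaults, class = "GrpmConfig")
}

#' @rdname grpmConfig
#' @param config A `GrpmConfig`.
#' @param path JSON file.
#' @export
writeGrpmConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname grpmConfig
#' @export
readGrpmConfig <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  # NA-valued keys serialise to null and vanish on read; grpmConfig()
  # restores them from the defaults (whose unset values are NA)
  grpmConfig(o)
}

## internal: split a held-out study into two "platform" subsets by
## alternating patient order (deterministic).
splitHoldout <- function(cohort, dosages) {
  d <- cohortData(cohort)
  half <- seq_len(nrow(d)) %% 2 == 1
  lapply(list(half, !half), function(idx) {
    sub <- SurvivalCohort(d[idx, , drop = FALSE], covariateNames(cohort))
    list(cohort = sub, dosages = dosages[d$patient_id[idx], , drop = FALSE])
  })
}

#' Run the full GRPM discovery pipeline on synthetic data
#'
#' Executes the whole chain — simulate, per-variant survival GWAS with
#' per-study meta-analysis, LD-aware gene scores, insulated-diffusion module
#' discovery with the two-stage permutation test (over the automatically
#' selected thresholds; the threshold with the smallest stage-1 P is
#' reported, ties broken toward the most stringent), per-module PHS construction (lasso selection on the designated
#' study, unpenalised refit), discovery + independent validation with
#' high-confidence selection, and downstream expression
#' correlation + pre-ranked GSEA for the high-confidence modules.
#'
#' The last study (or `holdoutStudy`) is held out of every training step and
#' analysed as two platform subsets combined by fixed-effects meta-analysis;
#' lasso selection runs on the largest remaining study unless
#' `phs$selectionStudy` is set.
#'
#' @param config A [grpmConfig()] object.
#' @param seed Global integer seed; per-stage seeds derive from it via
#'   [stageSeed()].
#' @param outDir Optional directory; when given, stage outputs are written
#'   as TSV/JSON files.
#' @return List: `data` (simulated inputs), `summary` (GWAS), `scores`
#'   (gene scores), `propagation` (per-delta permutation tests, chosen
#'   delta), `modules` (candidate modules), `phsModels`, `validation`
#'   (discovery/independent tables), `highConfidence` (module ids),
#'   `downstream` (per high-confidence module), and `report` (per-stage
#'   parameters, seeds, counts and warnings; sufficient to re-run
#'   bit-identically).
#' @export
runGrpmPipeline <- function(config = grpmConfig(), seed = 1L,
                            outDir = NULL) {
  stopifnot(inherits(config, "GrpmConfig"))
  report <- list(seed = seed, stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(stage = stage,
                                    seed = stageSeed(seed, stage), ...)
  }
  saveTsv <- function(df, name) {
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }

  ## a: simulate --------------------------------------------------------
  simArgs <- config$sim
  simArgs$seed <- stageSeed(seed, "simulate")
  data <- simulateGrpmData(do.call(simConfig, simArgs),
                           nGenes = config$nGenes,
                           nNetworkNodes = config$nNetworkNodes,
                           networkM = config$networkM,
                           moduleSize = config$moduleSize,
                           moduleMaxDegree = config$moduleMaxDegree,
                           logHr = config$logHr,
                           effectGroup = config$effectGroup,
                           expressionRho = config$expressionRho,
                           nPanel = config$nPanel)
  note("simulate", params = simArgs,
       counts = list(nPatients = length(data$cohort),
                     nVariants = ncol(data$dosages),
                     nGenes = config$nGenes))

  cohort <- subsetGroup(data$cohort, config$group)
  d <- cohortData(cohort)
  studies <- sort(unique(d$study))
  holdout <- if (is.na(config$holdoutStudy)) studies[length(studies)] else
    config$holdoutStudy
  discCohort <- SurvivalCohort(d[d$study != holdout, , drop = FALSE],
                               covariateNames(cohort))
  indCohort <- SurvivalCohort(d[d$study == holdout, , drop = FALSE],
                              covariateNames(cohort))

  ## b: survival GWAS on the discovery set ------------------------------
  summary <- runSurvivalGwas(discCohort, data$dosages, data$variants,
                             mafMin = config$gwas$mafMin,
                             infoMin = config$gwas$infoMin)
  saveTsv(summary, "gwas_summary.tsv")
  note("gwas", params = config$gwas,
       counts = list(nVariantsKept = nrow(summary),
                     nFiltered = attr(summary, "nFiltered"),
                     nDropped = attr(summary, "nDropped")))

  ## c: gene scores -----------------------------------------------------
  gs <- config$geneScores
  regions <- mapVariantsToGenes(data$annotation, data$variants,
                                window = gs$window,
                                excludeHla = gs$excludeHla)
  scores <- geneScores(summary, regions, data$panel, stat = gs$stat,
                       mcMin = gs$mcMin, mcCap = gs$mcCap,
                       seed = stageSeed(seed, "genescores"))
  saveTsv(scores, "gene_scores.tsv")
  note("genescores", params = gs,
       counts = list(nGenesScored = nrow(scores)))

  ## d: network propagation ---------------------------------------------
  pr <- config$propagation
  op <- buildDiffusion(data$network, beta = pr$beta)
  heats <- setNames(scores$heat, scores$gene)
  deltas <- selectDeltas(op, heats, nPerm = pr$nPermDelta,
                         sizes = pr$deltaSizes,
                         seed = stageSeed(seed, "deltas"))
  tests <- lapply(seq_along(deltas), function(i) {
    modulePermutationTest(op, heats, deltas[i], nPerm = pr$nPerm,
                          alpha = pr$alpha,
                          seed = stageSeed(seed, paste0("permtest", i)))
  })
  names(tests) <- names(deltas)
  minP <- vapply(tests, function(t) min(t$pValues$p), numeric(1))
  ## smallest stage-1 P wins; ties go to the largest (most stringent) delta,
  ## which yields the tightest modules
  best <- which(minP == min(minP))
  best <- best[which.max(deltas[best])]
  modules <- tests[[best]]$significantModules
  moduleTab <- if (length(modules)) data.frame(
    module_id = vapply(modules, `[[`, character(1), "id"),
    delta = deltas[best], size = vapply(modules, `[[`, integer(1), "size"),
    genes = vapply(modules, function(m) paste(m$genes, collapse = ";"),
                   character(1)),
    p_at_reporting_k = tests[[best]]$pValues$p[
      tests[[best]]$pValues$k == tests[[best]]$reportingK],
    stringsAsFactors = FALSE
  ) else data.frame()
  saveTsv(moduleTab, "modules.tsv")
  note("propagate", params = pr,
       counts = list(deltas = as.list(deltas), chosenDelta = names(best),
                     stage1MinP = as.list(minP),
                     nModules = length(modules),
                     nScoredGenesNotInNetwork =
                       attr(tests[[best]]$modules, "nDroppedScores")))

  ## e: PHS construction ------------------------------------------------
  selStudy <- config$phs$selectionStudy
  discStudies <- setdiff(studies, holdout)
  if (is.na(selStudy)) {
    selStudy <- discStudies[which.max(table(
      factor(cohortData(discCohort)$study, discStudies)))]
  }
  selCohort <- SurvivalCohort(
    cohortData(discCohort)[cohortData(discCohort)$study == selStudy, ,
                           drop = FALSE], covariateNames(cohort))
  phsModels <- list()
  for (m in modules) {
    pool <- moduleVariantPool(m$genes, regions,
                              keepVariants = summary$variant_id)
    if (!length(pool)) next
    sel <- tryCatch(
      lassoCoxSelect(data$dosages[patientIds(selCohort), pool,
                                  drop = FALSE],
                     selCohort, nfolds = config$phs$nfolds,
                     seed = stageSeed(seed, paste0("lasso", m$id))),
      grpmError = function(e) character())
    if (!length(sel)) next
    rs <- tryCatch(
      refitAndScore(sel, selCohort, data$dosages, data$variants,
                    moduleId = m$id, group = config$group),
      grpmError = function(e) NULL)
    if (is.null(rs)) next
    phsModels[[m$id]] <- rs$model
  }
  note("phs", params = list(nfolds = config$phs$nfolds,
                            selectionStudy = selStudy),
       counts = list(nModulesWithPhs = length(phsModels)))

  ## f: validation ------------------------------------------------------
  va <- config$validation
  subsets <- splitHoldout(indCohort, data$dosages)
  discRows <- list()
  indRows <- list()
  for (id in names(phsModels)) {
    mod <- phsModels[[id]]
    phsDisc <- applyPHS(mod, data$dosages[patientIds(discCohort), ,
                                          drop = FALSE])
    discRows[[id]] <- tryCatch(
      testPHS(phsDisc, discCohort, nPcs = va$nPcs, sdTrain = mod@trainSd,
              moduleId = id, dataset = "discovery"),
      grpmError = function(e) NULL)
    indRows[[id]] <- tryCatch(
      independentMeta(mod, subsets, nPcs = va$nPcs),
      grpmError = function(e) NULL)
  }
  drop <- vapply(names(phsModels), function(id)
    is.null(discRows[[id]]) || is.null(indRows[[id]]), logical(1))
  discovery <- do.call(rbind, discRows[!drop])
  independent <- do.call(rbind, indRows[!drop])
  highConfidence <- character()
  if (!is.null(discovery) && nrow(discovery)) {
    discovery$p_corrected <- bonferroni(discovery$p_one_sided,
                                        nrow(discovery))
    highConfidence <- selectHighConfidence(discovery, independent,
                                           alpha = va$alpha)
    discovery$verdict <- ifelse(discovery$module_id %in% highConfidence,
                                "high_confidence", "not_confirmed")
    saveTsv(discovery, "validation_discovery.tsv")
    saveTsv(independent, "validation_independent.tsv")
  }
  note("validate", params = va,
       counts = list(nTested = if (is.null(discovery)) 0 else
         nrow(discovery), nHighConfidence = length(highConfidence)))

  ## g: downstream enrichment -------------------------------------------
  ds <- config$downstream
  downstream <- list()
  if (isTRUE(ds$enabled)) {
    for (id in highConfidence) {
      phsAll <- applyPHS(phsModels[[id]],
                         data$dosages[rownames(data$expression), ,
                                      drop = FALSE])
      ranks <- downstreamScores(phsAll, data$expression)
      enr <- gseaPreranked(setNames(ranks$r, ranks$gene), data$geneSets,
                           weight = ds$weight, nPerm = ds$nPerm,
                           minSize = ds$minSize, maxSize = ds$maxSize,
                           seed = stageSeed(seed, paste0("gsea", id)))
      downstream[[id]] <- list(scores = ranks, enrichment = enr,
                               significant = filterEnriched(enr, ds$pMax,
                                                            ds$fdrMax))
      saveTsv(enr, paste0("enrichment_", id, ".tsv"))
    }
  }
  note("downstream", params = ds,
       counts = list(nModules = length(downstream)))

  if (!is.null(outDir)) {
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeGrpmConfig(config, file.path(outDir, "config.json"))
  }
  list(data = data, discoveryCohort = discCohort,
       independentCohort = indCohort, summary = summary, scores = scores,
       operator = op, propagation = list(deltas = deltas, tests = tests,
                                         chosen = names(deltas)[best]),
       modules = modules, phsModels = phsModels,
       validation = list(discovery = discovery, independent = independent),
       highConfidence = highConfidence, downstream = downstream,
       report = report)
}
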