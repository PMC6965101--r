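#' Candidate variant pool of a module
#'
#' The union, over the module's genes, of the member variants of each gene's
#' 50-kb window, deduplicated — the same variant selection used for the gene
#' scores (common variants within the window). Genes absent from the mapped
#' regions contribute nothing (with a warning).
#'
#' @param moduleGenes Character gene ids.
#' @param regions Gene regions from [mapVariantsToGenes()].
#' @param keepVariants Optional character vector restricting the pool (e.g.
#'   the MAF/info-filtered variants actually analysed).
#' @return Character vector of candidate variant ids (possibly empty).
#' @export
moduleVariantPool <- function(moduleGenes, regions, keepVariants = NULL) {
  absent <- setdiff(moduleGenes, names(regions))
  if (length(absent)) {
    warning("module genes absent from annotation/regions: ",
            paste(absent, collapse = ", "))
  }
  pool <- unique(unlist(lapply(regions[intersect(moduleGenes,
                                                 names(regions))],
                               `[[`, "variants")))
  if (!is.null(keepVariants)) pool <- intersect(pool, keepVariants)
  pool
}

## internal: event-stratified cross-validation folds; every fold is
## guaranteed at least one event (re-randomised up to 10 times, then error).
cvFolds <- function(event, nfolds, seed) {
  set.seed(seed)
  for (try in seq_len(10)) {
    foldid <- integer(length(event))
    for (grp in c(0, 1)) {
      idx <- which(event == grp)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    if (all(tabulate(foldid[event == 1], nfolds) > 0)) return(foldid)
  }
  grpmError("could not construct folds with events in every fold",
            "foldConstructionError")
}

#' Select a module's prognostic variants by L1-penalised Cox regression
#'
#' Fits a lasso (`alpha = 1`) Cox path on the candidate dosages with
#' delayed-entry survival and stratified baseline hazards, tunes the
#' penalty by cross-validated partial-likelihood deviance (folds stratified
#' by event status), and returns the variants with non-zero coefficients at
#' the deviance-minimising `lambda`.
#'
#' @param dosages Patient-by-candidate-variant dosage matrix aligned to (or
#'   row-named by) the cohort's patients.
#' @param cohort A [SurvivalCohort-class] (typically the designated selection
#'   study only).
#' @param nfolds Number of CV folds (default 10).
#' @param seed Integer seed (fold assignment).
#' @return Character vector of selected variant ids; empty when the path
#'   never picks a variant (the module is then not fittable).
#' @export
lassoCoxSelect <- function(dosages, cohort, nfolds = 10, seed = 1L) {
  if (nfolds < 2) grpmError("need >= 2 folds", "invalidConfigError")
  d <- cohortData(cohort)
  if (!is.null(rownames(dosages))) dosages <- dosages[d$patient_id, ,
                                                      drop = FALSE]
  stopifnot(nrow(dosages) == nrow(d))
  if (sum(d$event) < nfolds) {
    grpmError("fewer events than folds", "noInformationError")
  }
  keepCols <- which(apply(dosages, 2, sd) > 0)
  if (!length(keepCols)) return(character())
  x <- dosages[, keepCols, drop = FALSE]
  padded <- FALSE
  if (ncol(x) == 1) {           # glmnet needs >= 2 columns
    x <- cbind(x, .pad. = 0)
    padded <- TRUE
  }
  y <- glmnet::stratifySurv(survival::Surv(d$entry, d$exit, d$event),
                            d$stratum)
  foldid <- cvFolds(d$event, nfolds, seed)
  cv <- suppressWarnings(
    glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid,
                      nlambda = 30, lambda.min.ratio = 0.05))
  b <- as.matrix(coef(cv, s = "lambda.min"))[, 1]
  sel <- names(b)[b != 0]
  if (padded) sel <- setdiff(sel, ".pad.")
  sel
}

#' Refit unpenalised coefficients and compute the training PHS
#'
#' Jointly refits the selected variants in an unpenalised stratified Cox
#' model (with the cohort's covariates) and builds the module's polygenic
#' hazard score, `PHS = sum_i X_i beta_i`, storing the training-score mean
#' and SD so downstream hazard ratios can be reported per training SD.
#' Variants whose coefficient is inestimable (perfect collinearity) are
#' dropped with a warning.
#'
#' @param selected Character variant ids.
#' @param cohort A [SurvivalCohort-class] (training data).
#' @param dosages Patient-by-variant dosage matrix (row-named by patient).
#' @param variants Variant table supplying `alt`/`ref` (effect/other allele)
#'   and used to record allele orientation; optional columns ignored.
#' @param moduleId,group Metadata recorded in the model.
#' @param covariates,useStrata Adjustment configuration (as in
#'   [fitVariantCox()]).
#' @return List: `model` (a [PHSModel-class]) and `scores` (named numeric,
#'   training patients).
#' @export
refitAndScore <- function(selected, cohort, dosages, variants,
                          moduleId = "module", group = "all",
                          covariates = covariateNames(cohort),
                          useStrata = TRUE) {
  if (!length(selected)) grpmError("empty selection", "emptySelectionError")
  d <- cohortData(cohort)
  x <- dosages[d$patient_id, selected, drop = FALSE]
  df <- data.frame(entry = d$entry, exit = d$exit, event = d$event)
  vcols <- sprintf("V%d", seq_along(selected))
  df[vcols] <- as.data.frame(x)
  rhs <- paste(vcols, collapse = " + ")
  for (cv in covariates) {
    df[[cv]] <- d[[cv]]
    rhs <- paste(rhs, "+", cv)
  }
  if (useStrata) {
    df$.stratum <- d$stratum
    rhs <- paste(rhs, "+ strata(.stratum)")
  }
  fit <- tryCatch(
    survival::coxph(stats::as.formula(
      paste("Surv(entry, exit, event) ~", rhs)), data = df,
      ties = "breslow"),
    warning = function(w) {
      if (grepl("did not converge|infinite|singular",
                conditionMessage(w))) {
        grpmError(sprintf("unpenalised refit failed for module '%s': %s",
                          moduleId, conditionMessage(w)),
                  "convergenceError")
      }
      suppressWarnings(survival::coxph(stats::as.formula(
        paste("Surv(entry, exit, event) ~", rhs)), data = df,
        ties = "breslow"))
    }
  )
  beta <- coef(fit)[vcols]
  ok <- !is.na(beta)
  if (!all(ok)) {
    warning(sprintf("dropping %d collinear variant(s) from module '%s'",
                    sum(!ok), moduleId))
  }
  if (!any(ok)) grpmError("no estimable coefficient", "convergenceError")
  selected <- selected[ok]
  beta <- unname(beta[ok])
  scores <- as.vector(x[, ok, drop = FALSE] %*% beta)
  names(scores) <- d$patient_id
  vi <- variants[match(selected, variants$variant_id), ]
  model <- new("PHSModel", moduleId = moduleId, variants = selected,
               effectAllele = vi$alt, otherAllele = vi$ref,
               beta = beta,
               trainMaf = colMeans(x[, ok, drop = FALSE]) / 2,
               trainMean = mean(scores), trainSd = sd(scores),
               group = group)
  list(model = model, scores = scores)
}

#' Apply a polygenic hazard score to external genotypes
#'
#' Computes `PHS = sum_i X_i beta_i` with the training coefficients. Allele
#' orientation is checked per variant against the external variant table:
#' a swapped effect/other allele is handled by dosage reflection
#' (`X -> 2 - X`). Missing variants raise an error listing the ids unless
#' mean-dosage imputation is explicitly enabled, in which case the
#' training-frequency expectation `2 * MAF_train` is substituted (and
#' logged via a message).
#'
#' @param model A [PHSModel-class].
#' @param dosages External patient-by-variant dosage matrix.
#' @param variants Optional external variant table (`variant_id`, `ref`,
#'   `alt`) used for the allele check; when `NULL`, orientation is assumed
#'   to match.
#' @param imputeMissing Substitute `2 * MAF_train` for unresolvable variants.
#' @return Named numeric vector of per-patient scores.
#' @export
applyPHS <- function(model, dosages, variants = NULL,
                     imputeMissing = FALSE) {
  stopifnot(is(model, "PHSModel"))
  present <- model@variants %in% colnames(dosages)
  if (any(!present) && !imputeMissing) {
    grpmError(paste("variants unresolvable in external genotypes:",
                    paste(model@variants[!present], collapse = ", ")),
              "missingVariantError")
  }
  n <- nrow(dosages)
  scores <- numeric(n)
  for (i in seq_along(model@variants)) {
    v <- model@variants[i]
    if (!present[i]) {
      message("imputing mean dosage for missing variant ", v)
      scores <- scores + model@beta[i] * 2 * model@trainMaf[i]
      next
    }
    x <- dosages[, v]
    if (!is.null(variants)) {
      row <- variants[variants$variant_id == v, , drop = FALSE]
      if (nrow(row) == 1) {
        if (row$alt == model@effectAllele[i] &&
            row$ref == model@otherAllele[i]) {
          # orientation matches
        } else if (row$ref == model@effectAllele[i] &&
                   row$alt == model@otherAllele[i]) {
          x <- 2 - x          # alleles swapped: reflect the dosage
        } else {
          grpmError(paste("allele mismatch for variant", v),
                    "missingVariantError")
        }
      }
    }
    scores <- scores + model@beta[i] * x
  }
  names(scores) <- rownames(dosages)
  scores
}

#' Serialise a PHS model to JSON
#'
#' @param model A [PHSModel-class].
#' @param path Output file.
#' @param provenance Optional named list stored verbatim (seeds, settings).
#' @return `path`, invisibly.
#' @export
writePHSModel <- function(model, path, provenance = list()) {
  obj <- list(module_id = model@moduleId, group = model@group,
              variants = model@variants,
              effect_allele = model@effectAllele,
              other_allele = model@otherAllele, beta = model@beta,
              train_maf = unname(model@trainMaf),
              train_mean = model@trainMean, train_sd = model@trainSd,
              provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PHS model from JSON
#'
#' @param path JSON file written by [writePHSModel()].
#' @return A [PHSModel-class].
#' @export
readPHSModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PHSModel", moduleId = o$module_id, variants = o$variants,
      effectAllele = o$effect_allele, otherAllele = o$other_allele,
      beta = as.numeric(o$beta), trainMaf = as.numeric(o$train_maf),
      trainMean = o$train_mean, trainSd = o$train_sd, group = o$group)
}
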