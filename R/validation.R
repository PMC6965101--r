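#' Test a module's PHS against survival
#'
#' Fits a stratified Cox model to the PHS (adjusted for the leading
#' principal components) and reports a one-sided Wald P in the predefined
#' adverse direction — a higher PHS means worse survival, so the one-sided
#' P is `Phi(-z)` for `z = beta / se`. The hazard ratio is reported per
#' training-set standard deviation of the PHS.
#'
#' @param phs Named per-patient scores (names = patient ids).
#' @param cohort A [SurvivalCohort-class].
#' @param nPcs Number of leading PC covariates to adjust for (default 2).
#' @param useStrata Stratify by country (default TRUE).
#' @param sdTrain Training-PHS standard deviation used for the HR scale
#'   (default: SD of `phs` in this cohort).
#' @param moduleId,dataset Labels recorded in the result.
#' @return One-row data.frame: `module_id`, `dataset`, `beta`, `se`, `z`,
#'   `p_one_sided`, `hr_per_sd`, `ci95_low`, `ci95_high`, `n`, `n_events`.
#' @export
testPHS <- function(phs, cohort, nPcs = 2, useStrata = TRUE,
                    sdTrain = NULL, moduleId = "module",
                    dataset = "discovery") {
  d <- cohortData(cohort)
  phs <- phs[d$patient_id]
  if (anyNA(phs)) grpmError("PHS missing for some patients", "schemaError")
  if (sd(phs) == 0) grpmError("constant PHS", "degenerateScoreError")
  if (sum(d$event) < 1) grpmError("zero events", "noInformationError")
  if (is.null(sdTrain)) sdTrain <- sd(phs)
  covs <- head(covariateNames(cohort), nPcs)
  df <- data.frame(entry = d$entry, exit = d$exit, event = d$event,
                   phs = phs)
  rhs <- "phs"
  for (cv in covs) {
    df[[cv]] <- d[[cv]]
    rhs <- paste(rhs, "+", cv)
  }
  if (useStrata) {
    df$.stratum <- d$stratum
    rhs <- paste(rhs, "+ strata(.stratum)")
  }
  fit <- survival::coxph(stats::as.formula(
    paste("Surv(entry, exit, event) ~", rhs)), data = df, ties = "breslow")
  beta <- unname(coef(fit)["phs"])
  se <- unname(sqrt(diag(fit$var))[which(names(coef(fit)) == "phs")])
  z <- beta / se
  data.frame(
    module_id = moduleId, dataset = dataset, beta = beta, se = se, z = z,
    p_one_sided = pnorm(-z),
    hr_per_sd = exp(beta * sdTrain),
    ci95_low = exp((beta - 1.96 * se) * sdTrain),
    ci95_high = exp((beta + 1.96 * se) * sdTrain),
    n = nrow(d), n_events = sum(d$event), stringsAsFactors = FALSE
  )
}

#' Bonferroni correction
#'
#' `corrected P = min(1, P * nTests)`.
#'
#' @param p P value(s) in `(0, 1]`.
#' @param nTests Number of tests (`>= 1`).
#' @return Corrected P value(s), capped at 1.
#' @examples
#' bonferroni(4e-7, 21789)  # 0.0087, i.e. 0.01 at two decimals
#' @export
bonferroni <- function(p, nTests) {
  checkProb(p, "p")
  stopifnot(nTests >= 1)
  pmin(1, p * nTests)
}

#' Independent validation by two-subset fixed-effects meta-analysis
#'
#' Applies the PHS model to each independent subset (e.g. the two genotyping
#' platforms of a held-out study), tests each with [testPHS()] on the
#' log-hazard scale, combines by inverse-variance fixed-effects
#' meta-analysis, and recomputes the one-sided P from the combined z.
#' Subsets without events are dropped with a warning; if none remain an
#' error is raised.
#'
#' @param model A [PHSModel-class].
#' @param subsets List of lists, each with `cohort` (a
#'   [SurvivalCohort-class]), `dosages` and optionally `variants` (for the
#'   allele check in [applyPHS()]).
#' @param nPcs,useStrata Passed to [testPHS()].
#' @return One-row data.frame in the [testPHS()] layout with
#'   `dataset = "independent"` and an `n_subsets` column.
#' @export
independentMeta <- function(model, subsets, nPcs = 2, useStrata = TRUE) {
  rows <- list()
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    if (nEvents(s$cohort) < 1) {
      warning("independent subset ", i, " has no events; dropped")
      next
    }
    phs <- applyPHS(model, s$dosages, s$variants)
    rows[[length(rows) + 1]] <-
      testPHS(phs, s$cohort, nPcs, useStrata, sdTrain = model@trainSd,
              moduleId = model@moduleId, dataset = paste0("subset", i))
  }
  if (!length(rows)) grpmError("no independent subset with events",
                               "noInformationError")
  est <- do.call(rbind, rows)
  w <- 1 / est$se^2
  beta <- sum(w * est$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  data.frame(
    module_id = model@moduleId, dataset = "independent", beta = beta,
    se = se, z = z, p_one_sided = pnorm(-z),
    hr_per_sd = exp(beta * model@trainSd),
    ci95_low = exp((beta - 1.96 * se) * model@trainSd),
    ci95_high = exp((beta + 1.96 * se) * model@trainSd),
    n = sum(est$n), n_events = sum(est$n_events), n_subsets = nrow(est),
    stringsAsFactors = FALSE
  )
}

#' Select high-confidence modules
#'
#' A module is high confidence iff its discovery Bonferroni-corrected
#' one-sided P and its independent (meta-analysed) one-sided P are both
#' below `alpha`.
#'
#' @param discovery data.frame with `module_id` and `p_corrected`.
#' @param independent data.frame with `module_id` and `p_one_sided`.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of high-confidence module ids.
#' @export
selectHighConfidence <- function(discovery, independent, alpha = 0.05) {
  shared <- intersect(discovery$module_id, independent$module_id)
  keep <- vapply(shared, function(m) {
    discovery$p_corrected[discovery$module_id == m] < alpha &&
      independent$p_one_sided[independent$module_id == m] < alpha
  }, logical(1))
  shared[keep]
}
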