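#' Per-variant Cox proportional-hazards fit with delayed entry
#'
#' Fits a stratified Cox model to one variant's dosages with left-truncated
#' (delayed-entry) risk sets: a patient contributes to the risk set at event
#' time `t` iff `entry < t <= exit`. Ties are handled by the Breslow
#' approximation. Dosages (continuous in `[0, 2]`) enter directly as the
#' covariate, matching imputed-genotype practice.
#'
#' @param cohort A [SurvivalCohort-class].
#' @param dosage Numeric vector of per-patient dosages, aligned to
#'   `patientIds(cohort)` (or named by patient id).
#' @param covariates Covariate column names to adjust for (default: the
#'   cohort's covariates, i.e. principal components).
#' @param useStrata Stratify the baseline hazard by the cohort's `stratum`
#'   (country) label.
#' @param variantId Identifier recorded in the result row.
#' @return One-row data.frame (a variant effect): `variant_id`, `beta`, `se`,
#'   `z`, `p` (two-sided Wald), `n`, `n_events`, `study`.
#' @examples
#' cfg <- simConfig(nPatients = 300, nVariants = 5, seed = 2)
#' g <- generateGenotypes(cfg)
#' coh <- generateSurvival(g$dosages, plantedTruth(), cfg)
#' fitVariantCox(coh, g$dosages[patientIds(coh), 1])
#' @export
fitVariantCox <- function(cohort, dosage, covariates = covariateNames(cohort),
                          useStrata = TRUE, variantId = "variant") {
  d <- cohortData(cohort)
  if (!is.null(names(dosage))) dosage <- dosage[d$patient_id]
  stopifnot(length(dosage) == nrow(d))
  if (sum(d$event) < 1) grpmError("zero events", "noInformationError")
  if (sd(dosage) == 0) {
    grpmError("constant dosage (monomorphic variant)",
              "monomorphicVariantError")
  }
  x <- cbind(dosage = dosage)
  for (cv in covariates) x <- cbind(x, d[[cv]])
  colnames(x) <- c("dosage", covariates)
  strat <- if (useStrata) as.integer(factor(d$stratum)) else
    rep(1L, nrow(d))
  ctrl <- survival::coxph.control(iter.max = 50)
  fit <- withCallingHandlers(
    survival::agreg.fit(x, survival::Surv(d$entry, d$exit, d$event),
                        strata = strat, offset = NULL, init = NULL,
                        control = ctrl, weights = NULL,
                        method = "breslow", rownames = NULL),
    warning = function(w) invokeRestart("muffleWarning")
  )
  beta <- unname(fit$coefficients["dosage"])
  se <- unname(sqrt(diag(fit$var))[1])
  if (!is.finite(beta) || !is.finite(se) || fit$iter >= ctrl$iter.max) {
    grpmError(sprintf(
      "Cox fit failed to converge for %s (%d iterations, loglik %.4g)",
      variantId, fit$iter, fit$loglik[2]), "convergenceError")
  }
  z <- beta / se
  data.frame(variant_id = variantId, beta = beta, se = se, z = z,
             p = 2 * pnorm(-abs(z)), n = nrow(d), n_events = sum(d$event),
             study = "single", stringsAsFactors = FALSE)
}

#' Inverse-variance fixed-effects meta-analysis of variant effects
#'
#' Combines per-study log-hazard estimates with weights `w_k = 1 / se_k^2`:
#' `beta = sum(w beta) / sum(w)`, `se = sum(w)^-1/2`; the two-sided Wald P
#' is recomputed from the combined z.
#'
#' @param estimates data.frame of variant-effect rows (as returned by
#'   [fitVariantCox()]) for a single variant; requires `beta` and `se > 0`.
#' @return One-row data.frame with `study = "meta"` and `n_studies`.
#' @examples
#' e <- data.frame(variant_id = "v", beta = c(0.2, 0), se = c(0.1, 0.2),
#'                 n = c(100, 50), n_events = c(40, 20))
#' metaFixedEffects(e)  # beta 0.16, se ~0.0894
#' @export
metaFixedEffects <- function(estimates) {
  if (is.null(estimates) || nrow(estimates) == 0) {
    grpmError("no estimates to combine", "emptyMetaError")
  }
  stopifnot(all(estimates$se > 0))
  w <- 1 / estimates$se^2
  beta <- sum(w * estimates$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  data.frame(
    variant_id = estimates$variant_id[1], beta = beta, se = se, z = z,
    p = 2 * pnorm(-abs(z)),
    n = sum(estimates$n), n_events = sum(estimates$n_events),
    study = "meta", n_studies = nrow(estimates), stringsAsFactors = FALSE
  )
}

#' Filter variants on MAF and imputation quality
#'
#' Keeps a variant iff its overall MAF exceeds `mafMin` (strict) and its
#' imputation quality r-squared exceeds `infoMin` (strict) in at least one
#' study. The per-variant set of usable studies (info above threshold) is
#' returned so that meta-analysis combines only those studies.
#'
#' @param variants data.frame with `variant_id`, `maf` and one
#'   `info_<study>` column per study.
#' @param mafMin,infoMin Strict lower bounds (defaults 0.05 and 0.8).
#' @return List: `keep` (character variant ids) and `usableStudies` (named
#'   list mapping each kept variant to the study labels passing the info
#'   threshold).
#' @export
filterVariants <- function(variants, mafMin = 0.05, infoMin = 0.8) {
  infoCols <- grep("^info_", names(variants), value = TRUE)
  if (!length(infoCols)) {
    grpmError("no per-study info_* columns in variant table", "schemaError")
  }
  info <- as.matrix(variants[, infoCols, drop = FALSE])
  ok <- variants$maf > mafMin & apply(info, 1, max) > infoMin
  keep <- variants$variant_id[ok]
  studies <- sub("^info_", "", infoCols)
  usable <- lapply(which(ok), function(i) studies[info[i, ] > infoMin])
  names(usable) <- keep
  list(keep = keep, usableStudies = usable)
}

#' Genome-wide per-variant survival statistics with per-study meta-analysis
#'
#' Runs [fitVariantCox()] separately within each study (never a pooled fit),
#' then combines studies per variant by fixed-effects meta-analysis, using
#' only the studies where the variant's imputation quality passes the filter.
#' Variants failing the MAF/info filter, monomorphic within every usable
#' study, or non-convergent are dropped (counted in attributes).
#'
#' @param cohort A [SurvivalCohort-class] (already restricted to the subtype
#'   group of interest).
#' @param dosages Patient-by-variant dosage matrix; rows indexed by patient
#'   id.
#' @param variants Variant table (see [filterVariants()]); also supplies
#'   `chrom`, `pos`, alleles and `maf` for the output.
#' @param mafMin,infoMin Filter thresholds.
#' @param covariates,useStrata Passed to [fitVariantCox()].
#' @return data.frame of meta-analysed summary statistics: `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `maf`, `beta`, `se`,
#'   `z`, `p`, `n`, `n_events`, `n_studies`, `genomewide_significant`
#'   (P < 5e-8).
#' @export
runSurvivalGwas <- function(cohort, dosages, variants, mafMin = 0.05,
                            infoMin = 0.8,
                            covariates = covariateNames(cohort),
                            useStrata = TRUE) {
  d <- cohortData(cohort)
  dosages <- dosages[d$patient_id, , drop = FALSE]
  flt <- filterVariants(variants, mafMin, infoMin)
  studies <- sort(unique(d$study))
  byStudy <- lapply(setNames(studies, studies), function(s) {
    SurvivalCohort(d[d$study == s, , drop = FALSE], covariateNames(cohort))
  })
  rows <- vector("list", length(flt$keep))
  dropped <- 0L
  for (i in seq_along(flt$keep)) {
    v <- flt$keep[i]
    usable <- intersect(flt$usableStudies[[v]], studies)
    ests <- list()
    for (s in usable) {
      sub <- byStudy[[s]]
      dv <- dosages[patientIds(sub), v]
      est <- tryCatch(
        fitVariantCox(sub, dv, covariates, useStrata, variantId = v),
        grpmError = function(e) NULL
      )
      if (!is.null(est)) {
        est$study <- s
        ests[[s]] <- est
      }
    }
    if (!length(ests)) {
      dropped <- dropped + 1L
      next
    }
    rows[[i]] <- metaFixedEffects(do.call(rbind, ests))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) grpmError("no variant could be analysed",
                              "noInformationError")
  vi <- variants[match(out$variant_id, variants$variant_id), ]
  res <- data.frame(
    variant_id = out$variant_id, chrom = vi$chrom, pos = vi$pos,
    effect_allele = vi$alt, other_allele = vi$ref, maf = vi$maf,
    beta = out$beta, se = out$se, z = out$z, p = out$p, n = out$n,
    n_events = out$n_events, n_studies = out$n_studies,
    genomewide_significant = out$p < 5e-8, stringsAsFactors = FALSE
  )
  attr(res, "nFiltered") <- nrow(variants) - length(flt$keep)
  attr(res, "nDropped") <- dropped
  res
}
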