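#' @rdname SurvivalCohort-class
#' @param x,object A `SurvivalCohort`.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname SurvivalCohort-class
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname SurvivalCohort-class
#' @export
setGeneric("covariateNames", function(x) standardGeneric("covariateNames"))

#' @rdname SurvivalCohort-class
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Subset a cohort by tumour subtype group
#'
#' @param x A `SurvivalCohort`.
#' @param group One of `"all"`, `"er_pos"`, `"er_neg"`.
#' @return A `SurvivalCohort` restricted to the requested subtype.
#' @export
setGeneric("subsetGroup", function(x, group) standardGeneric("subsetGroup"))

#' @rdname DiffusionOperator-class
#' @param x,object A `DiffusionOperator`.
#' @export
setGeneric("diffusionMatrix", function(x) standardGeneric("diffusionMatrix"))

#' @rdname DiffusionOperator-class
#' @export
setGeneric("diffusionGenes", function(x) standardGeneric("diffusionGenes"))

#' @rdname PHSModel-class
#' @param x,object A `PHSModel`.
#' @export
setGeneric("phsVariants", function(x) standardGeneric("phsVariants"))

#' @rdname PHSModel-class
#' @export
setGeneric("phsCoefficients", function(x) standardGeneric("phsCoefficients"))

setMethod("patientIds", "SurvivalCohort", function(x) x@data$patient_id)
setMethod("cohortData", "SurvivalCohort", function(x) x@data)
setMethod("covariateNames", "SurvivalCohort", function(x) x@covariateNames)
setMethod("nEvents", "SurvivalCohort", function(x) sum(x@data$event))

setMethod("subsetGroup", "SurvivalCohort", function(x, group) {
  group <- match.arg(group, c("all", "er_pos", "er_neg"))
  if (group == "all") return(x)
  keep <- x@data$er_status == switch(group, er_pos = "positive",
                                     er_neg = "negative")
  SurvivalCohort(x@data[keep, , drop = FALSE], x@covariateNames)
})

setMethod("length", "SurvivalCohort", function(x) nrow(x@data))

setMethod("show", "SurvivalCohort", function(object) {
  d <- object@data
  cat(sprintf("SurvivalCohort: %d patients, %d events, %d strata, %d studies\n",
              nrow(d), sum(d$event), length(unique(d$stratum)),
              length(unique(d$study))))
  cat(sprintf("  follow-up %.2f-%.2f years; covariates: %s\n",
              min(d$exit), max(d$exit),
              if (length(object@covariateNames))
                paste(object@covariateNames, collapse = ", ") else "none"))
})

setMethod("diffusionMatrix", "DiffusionOperator", function(x) x@Fmat)
setMethod("diffusionGenes", "DiffusionOperator", function(x) x@genes)

setMethod("show", "DiffusionOperator", function(object) {
  cat(sprintf("DiffusionOperator: %d genes, beta = %.3f\n",
              length(object@genes), object@beta))
})

setMethod("phsVariants", "PHSModel", function(x) x@variants)
setMethod("phsCoefficients", "PHSModel",
          function(x) setNames(x@beta, x@variants))

setMethod("show", "PHSModel", function(object) {
  cat(sprintf("PHSModel '%s' (%s): %d variants, training PHS mean %.3f sd %.3f\n",
              object@moduleId, object@group, length(object@variants),
              object@trainMean, object@trainSd))
})
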