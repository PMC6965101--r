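#' @import methods
NULL

#' SurvivalCohort: left-truncated, right-censored patient follow-up
#'
#' Holds per-patient delayed-entry survival data for a cancer cohort:
#' entry and exit times in years since diagnosis, a cause-specific event
#' indicator, a stratification label (country), a study label, adjustment
#' covariates (genetic principal components) and a tumour subtype group
#' (estrogen-receptor status).
#'
#' @slot data data.frame with columns `patient_id`, `entry`, `exit`, `event`,
#'   `stratum`, `study`, `er_status`, plus one column per covariate.
#' @slot covariateNames character; names of covariate columns (may be empty).
#' @export
setClass("SurvivalCohort",
  representation(data = "data.frame", covariateNames = "character")
)

setValidity("SurvivalCohort", function(object) {
  d <- object@data
  need <- c("patient_id", "entry", "exit", "event", "stratum", "study",
            "er_status")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (length(bad <- setdiff(object@covariateNames, names(d)))) {
    return(paste("covariate columns absent:", paste(bad, collapse = ", ")))
  }
  if (any(!d$event %in% c(0, 1))) return("event must be 0/1")
  if (any(d$entry < 0) || any(d$entry >= d$exit)) {
    return("need 0 <= entry < exit for every patient")
  }
  if (anyNA(d$stratum) || anyNA(d$study)) {
    return("every patient needs a stratum and a study")
  }
  if (anyDuplicated(d$patient_id)) return("duplicated patient_id")
  TRUE
})

#' Construct a SurvivalCohort
#'
#' @param data data.frame with the columns documented in
#'   [SurvivalCohort-class].
#' @param covariateNames Character vector naming covariate columns in `data`
#'   (default: all columns matching `^pc[0-9]+$`).
#' @return A [SurvivalCohort-class] object.
#' @examples
#' d <- data.frame(patient_id = c("p1", "p2"), entry = 0, exit = c(3, 8),
#'                 event = c(1, 0), stratum = "c1", study = "s1",
#'                 er_status = "positive")
#' SurvivalCohort(d)
#' @export
SurvivalCohort <- function(data,
                           covariateNames = grep("^pc[0-9]+$", names(data),
                                                 value = TRUE)) {
  data$event <- as.numeric(data$event)
  new("SurvivalCohort", data = as.data.frame(data),
      covariateNames = covariateNames)
}

#' DiffusionOperator: insulated heat-diffusion matrix of a PPI network
#'
#' Encodes the HotNet2-style diffusion `F = beta * (I - (1 - beta) W)^-1`
#' restricted to the largest connected component of an undirected network,
#' where `W` is the column-normalised walk matrix and `beta` the restart
#' probability.
#'
#' @slot genes character; node ordering shared by `W` and `Fmat`.
#' @slot W column-stochastic walk matrix.
#' @slot beta restart probability in (0, 1].
#' @slot Fmat dense diffusion matrix; columns sum to one.
#' @export
setClass("DiffusionOperator",
  representation(genes = "character", W = "matrix", beta = "numeric",
                 Fmat = "matrix")
)

setValidity("DiffusionOperator", function(object) {
  n <- length(object@genes)
  if (!all(dim(object@W) == n) || !all(dim(object@Fmat) == n)) {
    return("W and Fmat must be n x n with n = length(genes)")
  }
  if (object@beta <= 0 || object@beta > 1) return("beta must lie in (0, 1]")
  if (any(object@Fmat < -1e-10)) return("Fmat entries must be non-negative")
  if (n > 0 && max(abs(colSums(object@Fmat) - 1)) > 1e-8) {
    return("Fmat columns must sum to 1")
  }
  TRUE
})

#' PHSModel: a module's polygenic hazard score
#'
#' A fitted polygenic hazard score for one module: the lasso-selected
#' variants, their unpenalised Cox log-hazard coefficients, the effect-allele
#' orientation each coefficient assumes, and the training-score
#' standardisation constants used to report hazard ratios per standard
#' deviation. The score of a patient with dosages `X` is the linear
#' predictor `sum_i X_i beta_i`.
#'
#' @slot moduleId character module identifier.
#' @slot variants character variant ids.
#' @slot effectAllele,otherAllele character; allele orientation of each dosage.
#' @slot beta numeric unpenalised Cox coefficients, one per variant.
#' @slot trainMaf numeric training-set allele frequency of the effect allele
#'   (used for optional mean-dosage imputation when transferring the score).
#' @slot trainMean,trainSd numeric; mean and SD of the training PHS.
#' @slot group character; tumour subtype group the model was trained in.
#' @export
setClass("PHSModel",
  representation(moduleId = "character", variants = "character",
                 effectAllele = "character", otherAllele = "character",
                 beta = "numeric", trainMaf = "numeric",
                 trainMean = "numeric", trainSd = "numeric",
                 group = "character")
)

setValidity("PHSModel", function(object) {
  n <- length(object@variants)
  if (n < 1) return("a usable PHS model needs >= 1 variant")
  if (length(object@beta) != n || length(object@effectAllele) != n ||
      length(object@otherAllele) != n || length(object@trainMaf) != n) {
    return("variants, alleles, beta and trainMaf must have equal length")
  }
  if (length(object@trainSd) != 1 || object@trainSd < 0) {
    return("trainSd must be a single non-negative number")
  }
  TRUE
})
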