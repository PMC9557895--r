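#' GrsCohort: dosages, variant weights and phenotypes in one object
#'
#' `GrsCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"dosage"` assay (variants in rows, individuals in columns),
#' per-variant weight information in `rowData()` (columns `effect_allele`,
#' `other_allele`, `weight`, `eaf`) and per-individual phenotypes/covariates
#' in `colData()`.  Scores added by [computeGrs()] live in `colData()` as
#' `grs` and `grs_decile`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [GrsCohort()] for construction from plain tables.
#' @export
setClass("GrsCohort", contains = "SummarizedExperiment")

setValidity("GrsCohort", function(object) {
  msgs <- character()
  if (!"dosage" %in% assayNames(object))
    msgs <- c(msgs, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (any(d < 0 | d > 2, na.rm = TRUE))
      msgs <- c(msgs, "dosages must lie in [0, 2] (or be NA)")
  }
  need <- c("effect_allele", "other_allele", "weight", "eaf")
  have <- colnames(rowData(object))
  if (!all(need %in% have))
    msgs <- c(msgs, sprintf("rowData must contain: %s",
                            paste(setdiff(need, have), collapse = ", ")))
  else {
    if (anyDuplicated(rownames(object)))
      msgs <- c(msgs, "variant ids (rownames) must be unique")
    eaf <- rowData(object)$eaf
    if (any(!is.finite(eaf) | eaf <= 0 | eaf >= 1))
      msgs <- c(msgs, "eaf must lie strictly inside (0, 1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GrsCohort from plain tables
#'
#' @param dosages numeric matrix of allele dosages in `[0, 2]`, individuals in
#'   rows and variants in columns (the orientation of the dosage TSV);
#'   dimnames give individual and variant ids.
#' @param weights data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`, `eaf`; one row per dosage column.
#' @param phenotypes data.frame with one row per individual; an `id` column,
#'   if present, must match the dosage rownames.
#'
#' @return A [GrsCohort-class] object.
#' @examples
#' cfg <- simConfig(n_individuals = 50, n_variants = 5, seed = 1)
#' sim <- simulateVariants(cfg)
#' pheno <- data.frame(bmi_raw = rnorm(50, 27, 4.5))
#' cohort <- GrsCohort(sim$dosages, sim$weights, pheno)
#' @export
GrsCohort <- function(dosages, weights, phenotypes) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  need <- c("variant_id", "effect_allele", "other_allele", "weight", "eaf")
  if (!all(need %in% names(weights)))
    .err(sprintf("weights table must contain: %s",
                 paste(setdiff(need, names(weights)), collapse = ", ")),
         "grsInvalidConfigError")
  if (is.null(colnames(dosages)))
    colnames(dosages) <- weights$variant_id
  miss <- setdiff(colnames(dosages), weights$variant_id)
  if (length(miss))
    .err(sprintf("no weight row for variant(s): %s",
                 paste(head(miss, 5L), collapse = ", ")),
         "grsMissingWeightError")
  weights <- weights[match(colnames(dosages), weights$variant_id), ]
  if (nrow(phenotypes) != nrow(dosages))
    .err("phenotype rows must match dosage rows (individuals)",
         "grsInvalidConfigError")
  ids <- rownames(dosages) %||% phenotypes[["id"]] %||%
    sprintf("ind_%05d", seq_len(nrow(dosages)))
  rd <- S4Vectors::DataFrame(weights[setdiff(need, "variant_id")],
                             row.names = weights$variant_id)
  cd <- S4Vectors::DataFrame(phenotypes[setdiff(names(phenotypes), "id")],
                             row.names = ids)
  se <- SummarizedExperiment(assays = list(dosage = t(dosages)),
                             rowData = rd, colData = cd)
  new("GrsCohort", se)
}

setMethod("show", "GrsCohort", function(object) {
  cat(sprintf("GrsCohort: %d variants x %d individuals\n",
              nrow(object), ncol(object)))
  w <- rowData(object)$weight
  cat(sprintf("  weights: %s (min %.4g, max %.4g)\n",
              if (all(w > 0)) "all increasing-allele oriented" else
                "mixed sign (recode before scoring)",
              min(w), max(w)))
  cat(sprintf("  colData: %s\n",
              paste(head(colnames(colData(object)), 12L), collapse = ", ")))
  if ("grs" %in% colnames(colData(object)))
    cat(sprintf("  grs: mean %.3f, sd %.3f (allele-count scale)\n",
                mean(colData(object)$grs, na.rm = TRUE),
                sd(colData(object)$grs, na.rm = TRUE)))
  invisible(NULL)
})

#' @describeIn GrsCohort-class dosage matrix, individuals in rows
#' @param object,x a `GrsCohort`
#' @export
dosageMatrix <- function(x) t(assay(x, "dosage"))

#' @describeIn GrsCohort-class per-variant weight table as a data.frame
#' @export
variantWeights <- function(x) {
  rd <- rowData(x)
  data.frame(variant_id = rownames(x),
             effect_allele = rd$effect_allele,
             other_allele = rd$other_allele,
             weight = rd$weight,
             eaf = rd$eaf,
             stringsAsFactors = FALSE)
}

#' @describeIn GrsCohort-class phenotypes/covariates (plus grs columns once
#'   computed) as a data.frame with an `id` column
#' @export
phenotypeTable <- function(x) {
  cd <- as.data.frame(colData(x))
  cbind(id = colnames(x), cd, stringsAsFactors = FALSE)
}

#' Fitted GRS-by-exposure interaction model
#'
#' Holds the interaction coefficient with its SE and P-value, the full
#' coefficient table, per-stratum per-allele associations, optional
#' genetic-risk decile contrasts and model metadata.
#'
#' @slot betaInt,seInt,pInt interaction coefficient, SE, two-sided P.
#' @slot coefficients full coefficient table (term, estimate, se, statistic, p).
#' @slot strata per-exposure-stratum per-allele beta/SE/P and N.
#' @slot decileContrasts exposure effect on the raw outcome within the bottom
#'   and top genetic-risk decile (kg/m^2), or NAs when not computed.
#' @slot n number of individuals in the pooled fit.
#' @slot meta list of model metadata (outcome, genetic term, exposure,
#'   covariates, keller flag).
#' @export
setClass("InteractionResult",
         representation(betaInt = "numeric", seInt = "numeric",
                        pInt = "numeric", coefficients = "data.frame",
                        strata = "data.frame", decileContrasts = "numeric",
                        n = "integer", meta = "list"))

setValidity("InteractionResult", function(object) {
  msgs <- character()
  if (!(object@pInt > 0 && object@pInt <= 1))
    msgs <- c(msgs, "pInt must lie in (0, 1]")
  if (object@seInt <= 0)
    msgs <- c(msgs, "seInt must be positive")
  if (nrow(object@strata) && sum(object@strata$n) != object@n)
    msgs <- c(msgs, "stratum Ns must sum to the analysis N")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "InteractionResult", function(object) {
  m <- object@meta
  cat(sprintf("InteractionResult: %s x %s on %s (n = %d%s)\n",
              m$genetic %||% "grs", m$exposure %||% "exposure",
              m$outcome %||% "outcome", object@n,
              if (isTRUE(m$keller)) ", Keller-adjusted" else ""))
  cat(sprintf("  beta_int = %.4g (SE %.3g), P = %s\n",
              object@betaInt, object@seInt, .formatP(object@pInt)))
  if (nrow(object@strata)) {
    cat("  per-allele association by stratum:\n")
    for (i in seq_len(nrow(object@strata)))
      cat(sprintf("    %s: beta = %.4g (SE %.3g), P = %s, n = %d\n",
                  object@strata$stratum[i], object@strata$beta[i],
                  object@strata$se[i], .formatP(object@strata$p[i]),
                  object@strata$n[i]))
  }
  if (!all(is.na(object@decileContrasts)))
    cat(sprintf("  exposure contrast: %+.3f kg/m^2 (bottom decile), %+.3f kg/m^2 (top decile)\n",
                object@decileContrasts[1L], object@decileContrasts[2L]))
  invisible(NULL)
})

#' Summary of a negative-control experiment series
#'
#' @slot R number of replicates requested.
#' @slot observedP interaction P-value of the real exposure (NA when the run
#'   was purely null-calibration).
#' @slot countBelow replicates with interaction P strictly below `observedP`.
#' @slot empiricalP `countBelow / R`.
#' @slot medianP interaction P of the median replicate; `medianIndex` its row.
#' @slot replicates per-replicate table: achieved group moments, interaction
#'   beta/SE/P, iterations, convergence flag.
#' @slot nFailed selections abandoned as infeasible (redrawn under the
#'   strict-R policy, otherwise excluded).
#' @slot meta list: group sizes, targets, tolerance, model description, seed.
#' @export
setClass("NegativeControlSummary",
         representation(R = "integer", observedP = "numeric",
                        countBelow = "integer", empiricalP = "numeric",
                        medianP = "numeric", medianIndex = "integer",
                        replicates = "data.frame", nFailed = "integer",
                        meta = "list"))

setValidity("NegativeControlSummary", function(object) {
  msgs <- character()
  if (object@countBelow < 0L || object@countBelow > object@R)
    msgs <- c(msgs, "countBelow must lie in [0, R]")
  if (!is.na(object@empiricalP) &&
      !isTRUE(all.equal(object@empiricalP, object@countBelow / object@R)))
    msgs <- c(msgs, "empiricalP must equal countBelow / R")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NegativeControlSummary", function(object) {
  cat(sprintf("NegativeControlSummary: %d replicates (%d failed selections)\n",
              object@R, object@nFailed))
  if (!is.na(object@observedP))
    cat(sprintf("  observed P = %s; %d/%d replicates below -> empirical P = %.3f\n",
                .formatP(object@observedP), object@countBelow, object@R,
                object@empiricalP))
  cat(sprintf("  median replicate P = %s (replicate %d)\n",
              .formatP(object@medianP), object@medianIndex))
  invisible(NULL)
})

#' @describeIn NegativeControlSummary-class replicate interaction P-values
#' @param x a `NegativeControlSummary`
#' @export
replicatePValues <- function(x) x@replicates$p[x@replicates$converged]
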