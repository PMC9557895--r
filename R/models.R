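# Linear models: stratified per-allele associations, the GRS-by-exposure
# interaction model (with the Keller covariate-interaction sensitivity
# variant), genetic-risk decile contrasts, per-variant scans and the
# allele-to-kilogram conversion.

.modelFrame <- function(object) {
  if (is(object, "GrsCohort")) as.data.frame(colData(object)) else
    as.data.frame(object)
}

.checkExposure <- function(e, name, constantClass = "grsInvalidSpecError") {
  u <- unique(e[!is.na(e)])
  if (length(u) < 2L)
    .err(sprintf("exposure '%s' has a single level in the analysis sample (empty stratum)",
                 name),
         constantClass)
  if (!all(u %in% c(0, 1)))
    .err(sprintf("exposure '%s' must be binary 0/1", name),
         "grsInvalidSpecError")
  invisible(TRUE)
}

# Shared interaction fit: outcome y, genetic term g, binary exposure E,
# covariate matrix C (no intercept; may have 0 columns).  The Keller variant
# adds every covariate-by-exposure and covariate-by-genetic product.
.interactionFit <- function(y, g, E, C, keller = FALSE) {
  X <- cbind(`(Intercept)` = 1, g = g, E = E, `g:E` = g * E)
  if (ncol(C)) {
    X <- cbind(X, C)
    if (keller) {
      CE <- C * E
      colnames(CE) <- paste0(colnames(C), ":E")
      Cg <- C * g
      colnames(Cg) <- paste0(colnames(C), ":g")
      X <- cbind(X, CE, Cg)
    }
  }
  fit <- .ols(X, y)
  int <- fit$coefficients[fit$coefficients$term == "g:E", ]
  list(betaInt = int$estimate, seInt = int$se, pInt = int$p,
       coefficients = fit$coefficients, n = fit$n, df = fit$df)
}

.analysisRows <- function(data, cols, subset = NULL) {
  keep <- complete.cases(data[cols])
  if (!is.null(subset)) keep <- keep & subset
  keep
}

#' @rdname fitStratifiedAssociation
#' @export
setGeneric("fitStratifiedAssociation",
           function(object, ...) standardGeneric("fitStratifiedAssociation"))

#' Per-allele association with the outcome, separately by exposure stratum
#'
#' Ordinary least squares of the outcome on the genetic term plus covariates
#' within each exposure level.  Rows with a missing exposure (e.g. the
#' treated flag outside cases) are excluded, so a within-cases exposure
#' automatically restricts the sample.
#'
#' @param object a [GrsCohort-class] (with `grs` computed) or a data.frame.
#' @param genetic column of the genetic term (GRS or a single-variant
#'   dosage).
#' @param outcome outcome column (default the inverse-normalized BMI).
#' @param exposure binary 0/1 exposure column defining the strata.
#' @param covariates covariate columns; factors expand to indicators with the
#'   most frequent level as reference.
#' @param subset optional logical vector restricting the analysis sample.
#' @param ... passed between methods.
#' @return data.frame: stratum, n, beta, se, p.
#' @export
setMethod("fitStratifiedAssociation", "ANY",
          function(object, genetic = "grs", outcome = "bmi_int",
                   exposure = "case", covariates = character(),
                   subset = NULL, ...) {
  data <- .modelFrame(object)
  cols <- c(outcome, genetic, exposure, covariates)
  keep <- .analysisRows(data, cols, subset)
  data <- data[keep, , drop = FALSE]
  .checkExposure(data[[exposure]], exposure,
                 constantClass = "grsEmptyGroupError")
  C <- .covariateMatrix(data, covariates)
  out <- lapply(sort(unique(data[[exposure]])), function(lv) {
    idx <- data[[exposure]] == lv
    if (!any(idx))
      .err(sprintf("stratum %s=%s is empty", exposure, lv),
           "grsEmptyGroupError")
    X <- cbind(`(Intercept)` = 1, g = data[[genetic]][idx],
               C[idx, , drop = FALSE])
    fit <- .ols(X, data[[outcome]][idx])
    co <- fit$coefficients[fit$coefficients$term == "g", ]
    data.frame(stratum = sprintf("%s=%s", exposure, lv), n = fit$n,
               beta = co$estimate, se = co$se, p = co$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
})

#' @rdname fitInteractionModel
#' @export
setGeneric("fitInteractionModel",
           function(object, ...) standardGeneric("fitInteractionModel"))

#' GRS-by-exposure interaction model
#'
#' Fits a single pooled linear model of the outcome on the genetic term, the
#' exposure, their product and the covariates; with `keller = TRUE` every
#' covariate-by-exposure and covariate-by-genetic product is added as well,
#' guarding against confounded interactions.  The embedded stratified fits
#' ([fitStratifiedAssociation()]) and, optionally, genetic-risk decile
#' contrasts ([decileContrast()]) are returned alongside.
#'
#' @inheritParams fitStratifiedAssociation
#' @param keller add covariate-by-exposure and covariate-by-genetic terms.
#' @param decileContrasts also compute bottom/top decile contrasts of
#'   `contrastOutcome` (default raw BMI).
#' @param decileColumn,contrastOutcome,adjustContrasts see [decileContrast()].
#' @return An [InteractionResult-class].
#' @examples
#' cohort <- simulateCohort(simConfig(n_individuals = 800, n_variants = 10,
#'                                    seed = 3))
#' cohort <- addTransformedBmi(computeGrs(cohort))
#' fitInteractionModel(cohort, covariates = c("age", "sex"))
#' @export
setMethod("fitInteractionModel", "ANY",
          function(object, genetic = "grs", exposure = "case",
                   outcome = "bmi_int", covariates = character(),
                   keller = FALSE, subset = NULL, decileContrasts = FALSE,
                   decileColumn = "grs_decile",
                   contrastOutcome = "bmi_raw", adjustContrasts = TRUE, ...) {
  data <- .modelFrame(object)
  cols <- c(outcome, genetic, exposure, covariates)
  keep <- .analysisRows(data, cols, subset)
  data <- data[keep, , drop = FALSE]
  .checkExposure(data[[exposure]], exposure)
  C <- .covariateMatrix(data, covariates)
  fit <- .interactionFit(data[[outcome]], data[[genetic]],
                         data[[exposure]], C, keller = keller)
  strata <- fitStratifiedAssociation(data, genetic = genetic,
                                     outcome = outcome, exposure = exposure,
                                     covariates = covariates)
  dc <- c(bottom = NA_real_, top = NA_real_)
  if (decileContrasts)
    dc <- decileContrast(data, exposure = exposure, covariates = covariates,
                         outcome = contrastOutcome,
                         decileColumn = decileColumn,
                         adjust = adjustContrasts)
  new("InteractionResult", betaInt = fit$betaInt, seInt = fit$seInt,
      pInt = fit$pInt, coefficients = fit$coefficients, strata = strata,
      decileContrasts = dc, n = as.integer(fit$n),
      meta = list(outcome = outcome, genetic = genetic, exposure = exposure,
                  covariates = covariates, keller = keller))
})

#' @rdname decileContrast
#' @export
setGeneric("decileContrast",
           function(object, ...) standardGeneric("decileContrast"))

#' Exposure contrast within the bottom and top genetic-risk decile
#'
#' Within decile 1 and decile 10 separately, fits (by default
#' covariate-adjusted) OLS of the raw outcome on the exposure and returns the
#' exposure coefficients — the extra kg/m^2 associated with exposure at the
#' lowest and highest genetic risk.
#'
#' @inheritParams fitStratifiedAssociation
#' @param outcome outcome column; raw BMI by default so contrasts are in
#'   kg/m^2.
#' @param decileColumn decile assignment column (from [computeGrs()]).
#' @param adjust adjust for covariates (`FALSE` gives raw group-mean
#'   differences).
#' @return named numeric: `bottom`, `top`.
#' @export
setMethod("decileContrast", "ANY",
          function(object, exposure = "case", covariates = character(),
                   outcome = "bmi_raw", decileColumn = "grs_decile",
                   adjust = TRUE, subset = NULL, ...) {
  data <- .modelFrame(object)
  cols <- c(outcome, exposure, decileColumn, covariates)
  keep <- .analysisRows(data, cols, subset)
  data <- data[keep, , drop = FALSE]
  .checkExposure(data[[exposure]], exposure)
  covs <- if (adjust) covariates else character()
  out <- vapply(c(bottom = 1L, top = 10L), function(d) {
    idx <- data[[decileColumn]] == d
    sub <- data[idx, , drop = FALSE]
    if (length(unique(sub[[exposure]])) < 2L)
      .err(sprintf("decile %d lacks both exposure levels", d),
           "grsEmptyCellError")
    C <- .covariateMatrix(sub, covs)
    X <- cbind(`(Intercept)` = 1, E = sub[[exposure]], C)
    fit <- .ols(X, sub[[outcome]])
    fit$coefficients$estimate[fit$coefficients$term == "E"]
  }, numeric(1))
  out
})

#' Per-variant interaction scan
#'
#' Repeats the interaction model with each variant's dosage in place of the
#' GRS, returning per-stratum per-allele associations and the interaction
#' P-value per variant, with a Bonferroni flag at `alpha / M` where `M` is
#' the number of variants actually tested.  Monomorphic variants are skipped
#' with a warning and recorded with NA results.
#'
#' @param x a [GrsCohort-class] (recoded; [computeGrs()] recodes on the fly
#'   if needed).
#' @inheritParams fitInteractionModel
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data.frame with one row per variant and attribute
#'   `"bonferroni_threshold"`.
#' @export
perSnpInteractionScan <- function(x, exposure = "case", outcome = "bmi_int",
                                  covariates = character(), keller = FALSE,
                                  subset = NULL, alpha = 0.05) {
  stopifnot(is(x, "GrsCohort"))
  if (any(rowData(x)$weight < 0))
    x <- recodeToIncreasingAllele(x)
  data <- .modelFrame(x)
  dos <- dosageMatrix(x)
  cols <- c(outcome, exposure, covariates)
  keep <- .analysisRows(data, cols, subset)
  data <- data[keep, , drop = FALSE]
  dos <- dos[keep, , drop = FALSE]
  .checkExposure(data[[exposure]], exposure)
  C <- .covariateMatrix(data, covariates)
  y <- data[[outcome]]
  E <- data[[exposure]]
  rows <- lapply(colnames(dos), function(v) {
    d <- dos[, v]
    base <- data.frame(variant_id = v, n = NA_integer_,
                       beta_0 = NA_real_, se_0 = NA_real_, p_0 = NA_real_,
                       beta_1 = NA_real_, se_1 = NA_real_, p_1 = NA_real_,
                       beta_int = NA_real_, se_int = NA_real_,
                       p_int = NA_real_, skipped = TRUE,
                       stringsAsFactors = FALSE)
    if (length(unique(d[!is.na(d)])) < 2L) {
      warning(sprintf("variant %s is monomorphic: skipped", v))
      return(base)
    }
    fit <- .interactionFit(y, d, E, C, keller = keller)
    st <- lapply(c(0, 1), function(lv) {
      idx <- E == lv & !is.na(d)
      X <- cbind(`(Intercept)` = 1, g = d[idx], C[idx, , drop = FALSE])
      f <- .ols(X, y[idx])
      f$coefficients[f$coefficients$term == "g", ]
    })
    data.frame(variant_id = v, n = fit$n,
               beta_0 = st[[1]]$estimate, se_0 = st[[1]]$se, p_0 = st[[1]]$p,
               beta_1 = st[[2]]$estimate, se_1 = st[[2]]$se, p_1 = st[[2]]$p,
               beta_int = fit$betaInt, se_int = fit$seInt, p_int = fit$pInt,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  mTested <- sum(!res$skipped)
  thr <- alpha / max(mTested, 1L)
  res$bonferroni <- !res$skipped & res$p_int < thr
  attr(res, "bonferroni_threshold") <- thr
  res
}

#' Convert a per-allele interaction effect to kilograms
#'
#' Back-transforms a per-allele effect on the inverse-normal BMI scale to raw
#' kg/m^2 via the raw-scale SD, multiplies by the allele count, and converts
#' to weight for a given height: `kg = beta * n_alleles * bmi_sd_raw *
#' height_m^2`.
#'
#' @param beta per-allele effect, inverse-normal BMI scale.
#' @param nAlleles number of additional trait-raising alleles (default 10).
#' @param heightM height in metres (default 1.73).
#' @param bmiSdRaw raw-scale BMI SD used for the back-transform (kg/m^2).
#' @return weight difference in kg.
#' @examples
#' betaToWeightChange(0.0255, nAlleles = 10, heightM = 1.73, bmiSdRaw = 4.6)
#' @export
betaToWeightChange <- function(beta, nAlleles = 10, heightM = 1.73,
                               bmiSdRaw) {
  .assertNumber(heightM, "heightM", lower = 1e-6)
  .assertNumber(bmiSdRaw, "bmiSdRaw", lower = 1e-6)
  beta * nAlleles * bmiSdRaw * heightM^2
}
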