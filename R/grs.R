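# GRS construction: recoding to the trait-increasing allele, the weighted
# score, the allele-count rescale and genetic-risk deciles.

#' Recode a variant panel to the trait-increasing allele
#'
#' Rows with a negative weight are flipped: the weight is negated, each
#' dosage becomes `2 - dosage`, and the effect/other allele labels swap.
#' Rows with positive weight are untouched.  The operation is idempotent and
#' the downstream GRS is invariant to the input orientation.
#'
#' @param weights weight table (`variant_id`, `effect_allele`,
#'   `other_allele`, `weight`, `eaf`).
#' @param dosages individuals x variants dosage matrix whose columns all have
#'   a weight row.
#' @return list with recoded `weights` and `dosages`.
#' @examples
#' w <- data.frame(variant_id = "v1", effect_allele = "A", other_allele = "G",
#'                 weight = -0.1, eaf = 0.3)
#' d <- matrix(1.5, 1, 1, dimnames = list("i1", "v1"))
#' recodePanel(w, d)   # weight +0.1, dosage 0.5
#' @export
recodePanel <- function(weights, dosages) {
  miss <- setdiff(colnames(dosages), weights$variant_id)
  if (length(miss))
    .err(sprintf("no weight row for variant(s): %s",
                 paste(head(miss, 5L), collapse = ", ")),
         "grsMissingWeightError")
  weights <- weights[match(colnames(dosages), weights$variant_id), ]
  flip <- weights$weight < 0
  if (any(flip)) {
    dosages[, flip] <- 2 - dosages[, flip]
    ea <- weights$effect_allele[flip]
    weights$effect_allele[flip] <- weights$other_allele[flip]
    weights$other_allele[flip] <- ea
    weights$eaf[flip] <- 1 - weights$eaf[flip]
    weights$weight[flip] <- -weights$weight[flip]
  }
  list(weights = weights, dosages = dosages)
}

#' Weighted GRS on the allele-count scale
#'
#' Per individual, the weighted score is `sum_j beta_j * dosage_j` over the
#' recoded (all-positive-weight) panel.  The returned GRS rescales it to
#' reflect the number of trait-increasing alleles: with `rescale =
#' "alleleCount"` (default) the score is multiplied by `M / sum(beta)` so an
#' individual homozygous for every increasing allele scores `2 * M`; with
#' `rescale = "sumBeta"` it is divided by `sum(beta)` only (the two differ by
#' the constant factor M and give identical regression P-values).
#'
#' Missing dosages are mean-imputed per variant at `2 * eaf`; individuals
#' with every dosage missing get an NA score and are reported via the
#' `"n_all_missing"` attribute.  The per-variant missingness fractions are
#' attached as attribute `"missingness"`.
#'
#' @param dosages recoded individuals x variants dosage matrix.
#' @param weights recoded weight table (all weights > 0).
#' @param rescale `"alleleCount"` or `"sumBeta"`.
#' @return numeric vector of scores, named by individual.
#' @examples
#' w <- data.frame(variant_id = c("a", "b", "c"),
#'                 effect_allele = "A", other_allele = "G",
#'                 weight = c(0.1, 0.2, 0.3), eaf = 0.5)
#' d <- matrix(c(2, 1, 0), 1, dimnames = list("i1", c("a", "b", "c")))
#' weightedGrs(d, w)   # 0.4 * 3 / 0.6 = 2
#' @export
weightedGrs <- function(dosages, weights,
                        rescale = c("alleleCount", "sumBeta")) {
  rescale <- match.arg(rescale)
  weights <- weights[match(colnames(dosages), weights$variant_id), ]
  if (any(is.na(weights$weight)))
    .err("every dosage column needs a weight row", "grsMissingWeightError")
  if (any(weights$weight < 0))
    .err("negative weights present; run recodePanel() first",
         "grsInvalidConfigError")
  allMissing <- rowSums(!is.na(dosages)) == 0L
  missFrac <- colMeans(is.na(dosages))
  if (any(missFrac > 0)) {
    imp <- 2 * weights$eaf
    for (j in which(missFrac > 0)) {
      nas <- is.na(dosages[, j])
      dosages[nas, j] <- imp[j]
    }
  }
  score <- as.vector(dosages %*% weights$weight)
  sb <- sum(weights$weight)
  grs <- if (rescale == "alleleCount") score * ncol(dosages) / sb else score / sb
  grs[allMissing] <- NA_real_
  names(grs) <- rownames(dosages)
  attr(grs, "missingness") <- setNames(missFrac, colnames(dosages))
  attr(grs, "n_all_missing") <- sum(allMissing)
  grs
}

#' Assign genetic-risk deciles
#'
#' Scores are ranked (ties broken by input order, i.e. individual-id order,
#' for determinism) and split into 10 near-equal groups; decile 1 is the
#' lowest 10% of genetic risk, decile 10 the highest.
#'
#' @param grs numeric vector of scores (NAs allowed; they get NA deciles).
#' @return integer vector of deciles 1-10.
#' @examples
#' assignDeciles(seq_len(100))   # 10 per decile
#' @export
assignDeciles <- function(grs) {
  ok <- !is.na(grs)
  n <- sum(ok)
  if (n < 10L)
    .err("need at least 10 non-missing scores to form deciles",
         "grsInsufficientDataError")
  r <- rank(grs[ok], ties.method = "first")
  dec <- rep(NA_integer_, length(grs))
  dec[ok] <- as.integer(ceiling(r * 10 / n))
  dec
}

#' @rdname recodeToIncreasingAllele
#' @export
setGeneric("recodeToIncreasingAllele",
           function(x, ...) standardGeneric("recodeToIncreasingAllele"))

#' Recode a GrsCohort to the trait-increasing allele
#'
#' Applies [recodePanel()] to the cohort's weight table and dosage assay.
#'
#' @param x a [GrsCohort-class].
#' @param ... unused.
#' @return the recoded object (same class as `x`).
#' @export
setMethod("recodeToIncreasingAllele", "GrsCohort", function(x, ...) {
  rec <- recodePanel(variantWeights(x), dosageMatrix(x))
  assay(x, "dosage") <- t(rec$dosages)
  rowData(x)$effect_allele <- rec$weights$effect_allele
  rowData(x)$other_allele <- rec$weights$other_allele
  rowData(x)$weight <- rec$weights$weight
  rowData(x)$eaf <- rec$weights$eaf
  validObject(x)
  x
})

#' @rdname computeGrs
#' @export
setGeneric("computeGrs", function(x, ...) standardGeneric("computeGrs"))

#' Compute the GRS and genetic-risk deciles for a cohort
#'
#' Recodes to the increasing allele if needed, computes the weighted,
#' allele-count-rescaled score ([weightedGrs()]) and decile assignment
#' ([assignDeciles()]), and stores them in `colData()` as `grs` and
#' `grs_decile`.
#'
#' @param x a [GrsCohort-class].
#' @param rescale passed to [weightedGrs()].
#' @param ... unused.
#' @return `x` with `grs` and `grs_decile` columns added.
#' @examples
#' cohort <- simulateCohort(simConfig(n_individuals = 200, n_variants = 10))
#' cohort <- computeGrs(cohort)
#' summary(colData(cohort)$grs)
#' @export
setMethod("computeGrs", "GrsCohort",
          function(x, rescale = c("alleleCount", "sumBeta"), ...) {
  rescale <- match.arg(rescale)
  if (any(rowData(x)$weight < 0))
    x <- recodeToIncreasingAllele(x)
  grs <- weightedGrs(dosageMatrix(x), variantWeights(x), rescale = rescale)
  if (attr(grs, "n_all_missing") > 0L)
    message(sprintf("%d individual(s) with all dosages missing: GRS set to NA",
                    attr(grs, "n_all_missing")))
  colData(x)$grs <- as.numeric(grs)
  if (sum(!is.na(grs)) >= 10L) {
    colData(x)$grs_decile <- assignDeciles(as.numeric(grs))
  } else {
    message("fewer than 10 scored individuals: no decile assignment")
    colData(x)$grs_decile <- NA_integer_
  }
  x
})
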