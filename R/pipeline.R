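# End-to-end orchestration: simulate (or load) -> GRS -> transform -> models
# -> negative controls -> TSV report + reproducibility manifest.

.table2Row <- function(label, contrasts, beta, se, pAssoc, pInt, n, nBelow) {
  data.frame(stratum = label,
             bmi_diff_bottom_decile = contrasts[1L],
             bmi_diff_top_decile = contrasts[2L],
             per_allele_beta = beta, se = se,
             p_association = .formatP(pAssoc),
             p_association_raw = pAssoc,
             p_interaction = .formatP(pInt),
             p_interaction_raw = pInt,
             n = n, n_negative_below = nBelow,
             stringsAsFactors = FALSE)
}

#' Run the full interaction + negative-control pipeline
#'
#' Simulates (or accepts) a cohort, computes the GRS and deciles, adds the
#' inverse-normalized outcome, and then, per exposure definition, fits the
#' interaction model with decile contrasts, optionally runs the
#' negative-control experiments and the per-variant scan, and writes all
#' results as TSVs plus a JSON manifest (config, seed, package version, file
#' checksums) that makes a rerun byte-identical.
#'
#' Exposure definitions: `"case"` (cases vs controls, full sample),
#' `"treated"` (treated vs untreated within cases; controls carry NA and drop
#' out), `"severity"` (above- vs below-median severity within cases).
#'
#' @param config a `"PipelineConfig"` (see [readPipelineConfig()]), a
#'   [simConfig()] object, or a [GrsCohort-class].
#' @param outdir output directory.
#' @param exposures subset of `c("case", "treated", "severity")`.
#' @param covariates covariate columns for all models.
#' @param keller use the Keller covariate-interaction adjustment.
#' @param negcontrolR negative-control replicates per exposure (0 skips).
#' @param tolerance,strictR negative-control settings.
#' @param perSnp also run the per-variant interaction scan (exposure
#'   `"case"`).
#' @param seed integer seed for the negative controls (the cohort's own seed
#'   lives in its SimConfig).
#' @return invisibly, a list with the cohort, per-exposure
#'   [InteractionResult-class] and [NegativeControlSummary-class] objects,
#'   and the manifest.
#' @examples
#' out <- runPipeline(simConfig(n_individuals = 400, n_variants = 8, seed = 5),
#'                    outdir = tempfile(), negcontrolR = 5, perSnp = FALSE,
#'                    covariates = c("age", "sex"))
#' @export
runPipeline <- function(config, outdir,
                        exposures = c("case", "treated", "severity"),
                        covariates = c("age", "sex", "centre", "tdi",
                                       paste0("pc", 1:5), "array"),
                        keller = FALSE, negcontrolR = 100L,
                        tolerance = 0.05, strictR = TRUE, perSnp = TRUE,
                        seed = 1L) {
  if (inherits(config, "PipelineConfig")) {
    exposures <- config$exposures
    covariates <- config$covariates
    keller <- config$keller
    negcontrolR <- config$negcontrol$R
    tolerance <- config$negcontrol$tolerance
    strictR <- config$negcontrol$strict_R
    perSnp <- config$perSnp
    seed <- config$seed
    config <- config$sim
  }
  exposures <- match.arg(exposures, c("case", "treated", "severity"),
                         several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (is(config, "GrsCohort")) config else simulateCohort(config)
  cohort <- addTransformedBmi(computeGrs(recodeToIncreasingAllele(cohort)))
  writeCohortTsv(cohort, outdir)

  expoCol <- c(case = "case", treated = "treated",
               severity = "severity_high")
  fits <- list()
  negs <- list()
  for (ex in exposures) {
    col <- expoCol[[ex]]
    if (!col %in% colnames(colData(cohort)))
      .err(sprintf("exposure column '%s' not present", col),
           "grsInvalidSpecError")
    fit <- fitInteractionModel(cohort, exposure = col,
                               covariates = covariates, keller = keller,
                               decileContrasts = TRUE)
    fits[[ex]] <- fit
    nBelow <- NA_character_
    if (negcontrolR > 0) {
      neg <- runNegativeExperiments(cohort, exposure = col,
                                    covariates = covariates,
                                    keller = keller, R = negcontrolR,
                                    tolerance = tolerance, seed = seed,
                                    strictR = strictR,
                                    observedP = fit@pInt)
      negs[[ex]] <- neg
      nBelow <- sprintf("%d/%d", neg@countBelow, neg@R)
      write.table(neg@replicates,
                  file.path(outdir,
                            sprintf("negcontrol_%s_replicates.tsv", ex)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      hdat <- negControlHistogram(neg)
      write.table(hdat,
                  file.path(outdir, sprintf("negcontrol_%s_histogram.tsv", ex)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- data.frame(exposure = ex, R = neg@R,
                         observed_p = neg@observedP,
                         count_below = neg@countBelow,
                         empirical_p = neg@empiricalP,
                         median_p = neg@medianP,
                         n_failed = neg@nFailed)
      write.table(summ,
                  file.path(outdir, sprintf("negcontrol_%s_summary.tsv", ex)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    st <- fit@strata
    ref <- st[1L, ]
    cmp <- st[2L, ]
    tab <- rbind(.table2Row(sprintf("%s (reference)", ref$stratum),
                            c(NA_real_, NA_real_), ref$beta, ref$se, ref$p,
                            NA_real_, ref$n, NA_character_),
                 .table2Row(cmp$stratum, fit@decileContrasts, cmp$beta,
                            cmp$se, cmp$p, fit@pInt, cmp$n, nBelow))
    write.table(tab, file.path(outdir, sprintf("table2_%s.tsv", ex)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (perSnp) {
    scan <- perSnpInteractionScan(cohort, exposure = "case",
                                  covariates = covariates, keller = keller)
    scan$p_int_formatted <- .formatP(scan$p_int)
    write.table(scan, file.path(outdir, "per_snp_case.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  cfgList <- if (inherits(config, "SimConfig")) unclass(config) else
    list(input = "GrsCohort")
  tsvs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(package = "grsInteract",
                   version = as.character(packageVersion("grsInteract")),
                   seed = seed, config = cfgList,
                   negcontrol = list(R = negcontrolR, tolerance = tolerance,
                                     strict_R = strictR),
                   covariates = covariates, keller = keller,
                   files = as.list(tools::md5sum(tsvs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, fits = fits, negcontrol = negs,
                 manifest = manifest))
}
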