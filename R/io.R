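# Plain-text I/O: the weights / dosage / phenotype TSV schemas, optional VCF
# dosage ingestion and the YAML pipeline config.

#' Write a cohort to TSV files
#'
#' Writes the three-table representation: `weights.tsv` (variant_id,
#' effect_allele, other_allele, weight, eaf), `dosages.tsv` (individuals x
#' variants, `id` column plus one column per variant) and `phenotypes.tsv`
#' (one row per individual).  Output is deterministic for a given cohort.
#'
#' @param x a [GrsCohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
writeCohortTsv <- function(x, dir) {
  stopifnot(is(x, "GrsCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("weights.tsv", "dosages.tsv", "phenotypes.tsv"))
  write.table(variantWeights(x), paths[1L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  dos <- dosageMatrix(x)
  write.table(cbind(data.frame(id = rownames(dos)), as.data.frame(dos)),
              paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(phenotypeTable(x), paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from TSV files
#'
#' @param weightsFile,dosagesFile,phenotypesFile paths to the three TSVs as
#'   written by [writeCohortTsv()].
#' @return A [GrsCohort-class].
#' @export
readCohort <- function(weightsFile, dosagesFile, phenotypesFile) {
  w <- read.delim(weightsFile, stringsAsFactors = FALSE)
  d <- read.delim(dosagesFile, stringsAsFactors = FALSE, check.names = FALSE)
  p <- read.delim(phenotypesFile, stringsAsFactors = FALSE)
  ids <- d$id
  d <- as.matrix(d[setdiff(names(d), "id")])
  rownames(d) <- ids
  GrsCohort(d, w, p)
}

#' Read dosages from a VCF
#'
#' Extracts per-genotype dosages (the `DS` FORMAT field when present,
#' otherwise the ALT-allele count from `GT`) and orients each variant to the
#' weight table's effect allele: when the effect allele is the REF allele the
#' dosage becomes `2 - dosage`; an effect allele matching neither REF nor
#' ALT is an error.
#'
#' @param path VCF path (plain or bgzipped; requires the vcfR package).
#' @param weights weight table with `variant_id` matching the VCF ID column.
#' @return individuals x variants dosage matrix.
#' @export
readDosageVcf <- function(path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    .err("readDosageVcf() requires the vcfR package", "grsInvalidInputError")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  fmt <- unique(unlist(strsplit(v@gt[, 1L], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2L, function(col)
      vapply(strsplit(col, "[/|]"), function(a) sum(a == "1"), numeric(1)))
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = length(ids))
  }
  rownames(ds) <- ids
  dos <- t(ds)  # individuals x variants
  w <- weights[match(colnames(dos), weights$variant_id), ]
  if (any(is.na(w$weight)))
    .err(sprintf("no weight row for VCF variant(s): %s",
                 paste(head(colnames(dos)[is.na(w$weight)], 5L),
                       collapse = ", ")),
         "grsMissingWeightError")
  for (j in seq_len(ncol(dos))) {
    ref <- fix[j, "REF"]; alt <- fix[j, "ALT"]
    ea <- w$effect_allele[j]
    if (ea == alt) next
    if (ea == ref) dos[, j] <- 2 - dos[, j]
    else .err(sprintf("effect allele %s of %s matches neither REF nor ALT",
                      ea, colnames(dos)[j]),
              "grsInvalidInputError")
  }
  dos
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds a `sim:` block (fields of [simConfig()]), an
#' `exposures:` list, a `covariates:` list, and a `negcontrol:` block
#' (`R`, `tolerance`, `strict_R`), plus `seed`.  Missing fields take the
#' package defaults.
#'
#' @param path YAML file path.
#' @return a list of class `"PipelineConfig"` for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(simConfig, y$sim %||% list())
  structure(list(sim = cfg,
                 exposures = unlist(y$exposures) %||% "case",
                 covariates = unlist(y$covariates) %||%
                   c("age", "sex", "centre", "tdi",
                     paste0("pc", 1:5), "array"),
                 keller = isTRUE(y$keller),
                 negcontrol = list(R = y$negcontrol$R %||% 100L,
                                   tolerance = y$negcontrol$tolerance %||% 0.05,
                                   strict_R = y$negcontrol$strict_R %||% TRUE),
                 perSnp = y$per_snp %||% TRUE,
                 seed = y$seed %||% cfg$seed),
            class = "PipelineConfig")
}
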