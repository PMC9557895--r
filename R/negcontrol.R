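# The negative-control engine: moment-matched disjoint group selection,
# replicate interaction testing, the empirical P and the summary-statistics
# simulation mode.

#' Select a subset matched to a target mean and SD
#'
#' Random-restart swap descent: starting from a random n-subset of the pool,
#' member/non-member swaps are proposed at random and accepted when they
#' reduce the loss `(mean - target_mean)^2 + (sd - target_sd)^2`; the search
#' stops as soon as both |achieved - target| differences are below
#' `tolerance`.  The default tolerance of 0.05 operationalizes matching "to
#' one decimal point".
#'
#' @param poolValues numeric outcome values of the pool; names (or positions)
#'   are the member ids.
#' @param n group size (>= 2).
#' @param targetMean,targetSd target moments (sample SD, denominator n-1).
#' @param tolerance convergence tolerance on both moments.
#' @param excludedIds ids (names or integer positions) excluded from the
#'   pool, e.g. a previously selected group.
#' @param seed optional seed; when NULL the current RNG state is used (so a
#'   caller can manage seeding across replicates).
#' @param maxIter total swap proposals across restarts.
#' @param restarts number of random restarts within `maxIter`.
#' @return integer vector of selected positions (into the original pool),
#'   with the achieved `mean`, `sd` and `iterations` as attributes.
#'   Raises a condition of class `"grsInfeasibleError"` carrying the
#'   best-achieved moments when the targets cannot be met.
#' @examples
#' pool <- rnorm(500, 27, 4.5)
#' idx <- selectMatchedGroup(pool, 100, 28, 5, seed = 1)
#' c(mean(pool[idx]), sd(pool[idx]))
#' @export
selectMatchedGroup <- function(poolValues, n, targetMean, targetSd,
                               tolerance = 0.05, excludedIds = NULL,
                               seed = NULL, maxIter = 100000L,
                               restarts = 3L) {
  if (!is.null(seed)) set.seed(seed)
  .assertNumber(tolerance, "tolerance", lower = 1e-12)
  .assertNumber(targetSd, "targetSd", lower = 1e-12)
  ids <- names(poolValues) %||% as.character(seq_along(poolValues))
  avail <- seq_along(poolValues)
  if (!is.null(excludedIds)) {
    excl <- if (is.numeric(excludedIds)) as.integer(excludedIds) else
      match(excludedIds, ids)
    avail <- setdiff(avail, excl)
  }
  pool <- poolValues[avail]
  if (any(!is.finite(pool)))
    .err("pool values must be finite", "grsInvalidInputError")
  if (n < 2L || n > length(pool))
    .err(sprintf("group size %d out of range for a pool of %d", n,
                 length(pool)),
         "grsInvalidInputError")
  if (targetMean > max(pool) || targetMean < min(pool))
    .err(sprintf("target mean %.3f outside the pool range [%.3f, %.3f]",
                 targetMean, min(pool), max(pool)),
         "grsInfeasibleError", mean = targetMean, sd = NA_real_)
  if (n == length(pool)) {
    res <- list(indices = seq_along(pool), mean = mean(pool), sd = sd(pool),
                iterations = 0L,
                converged = abs(mean(pool) - targetMean) < tolerance &&
                  abs(sd(pool) - targetSd) < tolerance)
  } else {
    res <- .selectMatchedCpp(as.numeric(pool), as.integer(n), targetMean,
                             targetSd, tolerance, as.integer(maxIter),
                             as.integer(restarts))
  }
  if (!res$converged)
    .err(sprintf(paste0("matched-group selection did not converge in %d ",
                        "iterations (best mean %.3f vs %.3f, sd %.3f vs %.3f)"),
                 res$iterations, res$mean, targetMean, res$sd, targetSd),
         "grsInfeasibleError", mean = res$mean, sd = res$sd)
  out <- avail[res$indices]
  attr(out, "mean") <- res$mean
  attr(out, "sd") <- res$sd
  attr(out, "iterations") <- res$iterations
  out
}

#' Empirical P-value from negative-control counts
#'
#' The plain proportion of negative experiments whose interaction P fell
#' strictly below the observed one: `countBelow / R` (no +1 correction).
#'
#' @param countBelow replicates with interaction P < observed.
#' @param R number of replicates.
#' @return `countBelow / R`.
#' @examples
#' empiricalP(67, 1000)   # 0.067
#' @export
empiricalP <- function(countBelow, R) {
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 1)
    .err("R must be a positive count", "grsInvalidInputError")
  if (!is.numeric(countBelow) || length(countBelow) != 1L ||
      is.na(countBelow) || countBelow < 0 || countBelow > R)
    .err("countBelow must lie in [0, R]", "grsInvalidInputError")
  countBelow / R
}

#' The median replicate by interaction P-value
#'
#' Returns the replicate whose P is the middle order statistic; for an even
#' count, the lower of the two middle replicates (a deterministic tie rule).
#'
#' @param replicatePs replicate interaction P-values.
#' @return list with `index` (into `replicatePs`) and `p`.
#' @examples
#' medianReplicate(c(0.1, 0.5, 0.9))$p        # 0.5
#' medianReplicate(c(0.1, 0.2, 0.3, 0.4))$p   # 0.2 (lower middle)
#' @export
medianReplicate <- function(replicatePs) {
  ps <- replicatePs[!is.na(replicatePs)]
  if (length(ps) == 0L)
    .err("no converged replicates", "grsEmptyGroupError")
  ord <- order(replicatePs[!is.na(replicatePs)])
  pos <- which(!is.na(replicatePs))
  m <- length(ps)
  k <- if (m %% 2L == 1L) (m + 1L) %/% 2L else m %/% 2L
  idx <- pos[ord[k]]
  list(index = idx, p = replicatePs[idx])
}

#' @rdname runNegativeExperiments
#' @export
setGeneric("runNegativeExperiments",
           function(object, ...) standardGeneric("runNegativeExperiments"))

#' Moment-matched negative-control experiments
#'
#' Repeatedly (R times) selects two disjoint pseudo-exposure groups from the
#' full analysis pool — group sizes and target outcome mean/SD taken from the
#' real exposure groups (or supplied) — refits the same interaction model
#' with group membership as the exposure, and summarises the replicate
#' interaction P-values.  Because the pseudo-groups reproduce the outcome
#' distributions but are random with respect to genotype-linked exposure,
#' the replicate P-values form an empirical null that retains any purely
#' distributional artefact; the empirical P is the proportion of replicates
#' beating the observed P.
#'
#' @param object a [GrsCohort-class] (with `grs`/`bmi_int` computed) or a
#'   data.frame.
#' @inheritParams fitInteractionModel
#' @param matchOn column whose distribution the pseudo-groups match (raw BMI
#'   by default).
#' @param R number of replicates.
#' @param tolerance moment-matching tolerance (see [selectMatchedGroup()]).
#' @param seed integer seed; replicate r uses a seed derived by counter so
#'   runs are reproducible and independent of scheduling.
#' @param maxIter,restarts passed to [selectMatchedGroup()].
#' @param strictR if TRUE (default), infeasible selections are redrawn so
#'   exactly R converged replicates are reported; if FALSE failures are
#'   logged and excluded.  More than 50% failures aborts with an
#'   infeasibility error either way.
#' @param targets optional list(mean1, sd1, mean2, sd2) overriding the real
#'   groups' moments; `groupSizes` likewise as c(n1, n2).
#' @param groupSizes optional c(n1, n2).
#' @param observedP optional observed interaction P; computed from the real
#'   exposure when NULL.
#' @param replicateCovariates if FALSE, replicate models drop the covariates
#'   (the observed model keeps them).
#' @return A [NegativeControlSummary-class].
#' @examples
#' cohort <- simulateCohort(simConfig(n_individuals = 600, n_variants = 10,
#'                                    seed = 11))
#' cohort <- addTransformedBmi(computeGrs(cohort))
#' runNegativeExperiments(cohort, R = 5, seed = 1)
#' @export
setMethod("runNegativeExperiments", "ANY",
          function(object, exposure = "case", genetic = "grs",
                   outcome = "bmi_int", matchOn = "bmi_raw",
                   covariates = character(), keller = FALSE, subset = NULL,
                   R = 1000L, tolerance = 0.05, seed = 1L,
                   maxIter = 100000L, restarts = 3L, strictR = TRUE,
                   targets = NULL, groupSizes = NULL, observedP = NULL,
                   replicateCovariates = TRUE, ...) {
  .assertNumber(R, "R", lower = 1)
  .assertNumber(seed, "seed", lower = 0, upper = 2^30)
  R <- as.integer(R)
  data <- .modelFrame(object)
  cols <- c(outcome, genetic, exposure, matchOn, covariates)
  keep <- .analysisRows(data, cols, subset)
  data <- data[keep, , drop = FALSE]
  .checkExposure(data[[exposure]], exposure)
  E <- data[[exposure]]
  bmi <- data[[matchOn]]
  if (is.null(groupSizes))
    groupSizes <- c(sum(E == 1), sum(E == 0))
  if (is.null(targets))
    targets <- list(mean1 = mean(bmi[E == 1]), sd1 = sd(bmi[E == 1]),
                    mean2 = mean(bmi[E == 0]), sd2 = sd(bmi[E == 0]))
  C <- .covariateMatrix(data, covariates)
  y <- data[[outcome]]
  g <- data[[genetic]]
  if (is.null(observedP)) {
    obs <- .interactionFit(y, g, E, C, keller = keller)
    observedP <- obs$pInt
  }
  Crep <- if (replicateCovariates) C else
    matrix(numeric(0), nrow = nrow(data), ncol = 0L)

  rows <- vector("list", R)
  nFailed <- 0L
  attempt <- 0L
  maxAttempts <- if (strictR) 3L * R else R
  r <- 1L
  while (r <= R && attempt < maxAttempts) {
    attempt <- attempt + 1L
    set.seed(seed + attempt)
    sel <- tryCatch({
      idx1 <- selectMatchedGroup(bmi, groupSizes[1L], targets$mean1,
                                 targets$sd1, tolerance = tolerance,
                                 maxIter = maxIter, restarts = restarts)
      idx2 <- selectMatchedGroup(bmi, groupSizes[2L], targets$mean2,
                                 targets$sd2, tolerance = tolerance,
                                 excludedIds = idx1, maxIter = maxIter,
                                 restarts = restarts)
      list(idx1 = idx1, idx2 = idx2)
    }, grsInfeasibleError = function(e) e)
    if (inherits(sel, "error")) {
      nFailed <- nFailed + 1L
      if (!strictR) {
        rows[[r]] <- data.frame(replicate = r, mean1 = NA_real_,
                                sd1 = NA_real_, mean2 = NA_real_,
                                sd2 = NA_real_, beta = NA_real_,
                                se = NA_real_, p = NA_real_,
                                iterations = NA_integer_, converged = FALSE)
        r <- r + 1L
      }
      if (nFailed > maxAttempts / 2)
        .err(sprintf(paste0("negative-control selection infeasible: %d of %d ",
                            "attempts failed to match the target moments"),
                     nFailed, attempt),
             "grsInfeasibleError")
      next
    }
    selIdx <- c(sel$idx1, sel$idx2)
    Eps <- c(rep(1, length(sel$idx1)), rep(0, length(sel$idx2)))
    fit <- .interactionFit(y[selIdx], g[selIdx], Eps,
                           Crep[selIdx, , drop = FALSE], keller = keller)
    rows[[r]] <- data.frame(replicate = r,
                            mean1 = attr(sel$idx1, "mean"),
                            sd1 = attr(sel$idx1, "sd"),
                            mean2 = attr(sel$idx2, "mean"),
                            sd2 = attr(sel$idx2, "sd"),
                            beta = fit$betaInt, se = fit$seInt, p = fit$pInt,
                            iterations = attr(sel$idx1, "iterations") +
                              attr(sel$idx2, "iterations"),
                            converged = TRUE)
    r <- r + 1L
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (strictR && length(rows) < R)
    .err(sprintf("only %d of %d replicates converged within the attempt budget",
                 length(rows), R),
         "grsInfeasibleError")
  reps <- do.call(rbind, rows)
  conv <- reps$converged
  if (!any(conv))
    .err("no converged negative-control replicates", "grsInfeasibleError")
  Reff <- sum(conv)
  countBelow <- sum(reps$p[conv] < observedP)
  med <- medianReplicate(ifelse(conv, reps$p, NA_real_))
  new("NegativeControlSummary", R = as.integer(Reff),
      observedP = observedP, countBelow = as.integer(countBelow),
      empiricalP = empiricalP(countBelow, Reff),
      medianP = med$p, medianIndex = as.integer(med$index),
      replicates = reps, nFailed = nFailed,
      meta = list(groupSizes = groupSizes, targets = targets,
                  tolerance = tolerance, exposure = exposure,
                  genetic = genetic, outcome = outcome, matchOn = matchOn,
                  covariates = covariates, keller = keller, seed = seed,
                  strictR = strictR, requestedR = R))
})

#' Negative controls from published summary statistics
#'
#' When only group sizes and outcome moments of an external study are
#' available, each replicate draws the outcome for two groups from
#' `Normal(mean, sd)`, draws genotypes independently of group (the null),
#' computes the GRS and fits the interaction of group membership with the
#' GRS on the outcome.  With genotype independent of group, the replicate
#' P-values calibrate the test's type-I error; against a supplied
#' `observedP` they give an empirical P for the published interaction.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 group sizes and outcome moments.
#' @param weights optional weight table (variant_id, weight, eaf); when NULL
#'   a panel of `nVariants` variants is generated from the seed.
#' @param nVariants,alleleFreqRange,weightScale panel parameters used when
#'   `weights` is NULL.
#' @param R number of replicates.
#' @param seed integer seed.
#' @param observedP optional observed interaction P to count against.
#' @param applyInt inverse-normal transform the simulated outcome before
#'   fitting.
#' @return A [NegativeControlSummary-class]; `meta$rejection_rate` holds the
#'   replicate rejection rate at alpha = 0.05.
#' @examples
#' simulateGroupsFromSummary(150, 27.2, 5.1, 300, 26.6, 4.4, R = 20, seed = 1)
#' @export
simulateGroupsFromSummary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                      weights = NULL, nVariants = 20L,
                                      alleleFreqRange = c(0.05, 0.95),
                                      weightScale = 0.03, R = 1000L,
                                      seed = 1L, observedP = NA_real_,
                                      applyInt = FALSE) {
  for (nm in c("n1", "n2"))
    .assertNumber(get(nm), nm, lower = 2)
  for (nm in c("sd1", "sd2"))
    .assertNumber(get(nm), nm, lower = 1e-12)
  .assertNumber(R, "R", lower = 1)
  .assertNumber(seed, "seed", lower = 0, upper = 2^30)
  R <- as.integer(R)
  if (is.null(weights)) {
    cfg <- simConfig(n_individuals = 1, n_variants = nVariants,
                     allele_freq_range = alleleFreqRange,
                     weight_scale = weightScale, seed = seed)
    weights <- simulateVariants(cfg)$weights
  }
  n <- n1 + n2
  E <- c(rep(1, n1), rep(0, n2))
  rows <- lapply(seq_len(R), function(r) {
    set.seed(seed + r)
    bmi <- c(rnorm(n1, mean1, sd1), rnorm(n2, mean2, sd2))
    dos <- matrix(rbinom(n * nrow(weights), 2L,
                         rep(weights$eaf, each = n)),
                  nrow = n, dimnames = list(NULL, weights$variant_id))
    grs <- as.numeric(weightedGrs(dos, weights))
    yy <- if (applyInt) inverseNormalTransform(bmi) else bmi
    fit <- .interactionFit(yy, grs, E,
                           matrix(numeric(0), nrow = n, ncol = 0L))
    data.frame(replicate = r,
               mean1 = mean(bmi[E == 1]), sd1 = sd(bmi[E == 1]),
               mean2 = mean(bmi[E == 0]), sd2 = sd(bmi[E == 0]),
               beta = fit$betaInt, se = fit$seInt, p = fit$pInt,
               iterations = 0L, converged = TRUE)
  })
  reps <- do.call(rbind, rows)
  countBelow <- if (is.na(observedP)) 0L else sum(reps$p < observedP)
  med <- medianReplicate(reps$p)
  new("NegativeControlSummary", R = R, observedP = observedP,
      countBelow = as.integer(countBelow),
      empiricalP = if (is.na(observedP)) NA_real_ else
        empiricalP(countBelow, R),
      medianP = med$p, medianIndex = as.integer(med$index),
      replicates = reps, nFailed = 0L,
      meta = list(groupSizes = c(n1, n2),
                  targets = list(mean1 = mean1, sd1 = sd1,
                                 mean2 = mean2, sd2 = sd2),
                  mode = "summary", seed = seed,
                  rejection_rate = mean(reps$p < 0.05)))
}

#' Histogram data for replicate -log10 P-values
#'
#' Bin edges and counts of `-log10(P)` across converged replicates, with the
#' observed and median replicate positions attached for annotation — the
#' ingredients of the standard negative-control figure.
#'
#' @param x a [NegativeControlSummary-class].
#' @param binwidth bin width on the -log10 scale.
#' @return data.frame (bin_start, bin_end, count) with attributes
#'   `"observed_log10p"` and `"median_log10p"`.
#' @export
negControlHistogram <- function(x, binwidth = 0.25) {
  stopifnot(is(x, "NegativeControlSummary"))
  lp <- -log10(replicatePValues(x))
  breaks <- seq(0, max(lp, 1) + binwidth, by = binwidth)
  h <- hist(lp, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_start = h$breaks[-length(h$breaks)],
                    bin_end = h$breaks[-1L], count = h$counts)
  attr(out, "observed_log10p") <- if (is.na(x@observedP)) NA_real_ else
    -log10(x@observedP)
  attr(out, "median_log10p") <- -log10(x@medianP)
  out
}
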