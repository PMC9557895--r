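# Outcome preparation: rank-based inverse normal transformation and the
# severity median split.

#' Rank-based inverse normal transformation
#'
#' Maps values through `qnorm((rank - offset) / (n - 2*offset + 1))` with the
#' Blom offset 3/8 by default, i.e. `qnorm((r - 3/8) / (n + 1/4))`.  Tied
#' values share the average rank.  NAs propagate; the transform uses the
#' non-missing values only.
#'
#' @param values numeric vector with at least 3 finite values.
#' @param offset rank offset; 3/8 (Blom) is the GWAS-standard choice.
#' @return numeric vector, approximately standard normal for continuous
#'   input.
#' @examples
#' inverseNormalTransform(c(1, 2, 3))   # middle value maps to 0
#' @export
inverseNormalTransform <- function(values, offset = 3/8) {
  ok <- is.finite(values)
  n <- sum(ok)
  if (n < 3L)
    .err("need at least 3 finite values", "grsInsufficientDataError")
  v <- values[ok]
  if (diff(range(v)) == 0)
    .err("all values identical: inverse normal transform is undefined",
         "grsDegenerateInputError")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Median split of a severity score
#'
#' The threshold is the median of the case scores; the indicator is 1 for
#' scores at or above it (mirroring a "below median (< t)" vs "above median
#' (>= t)" grouping).  When every score is equal the split is degenerate:
#' everyone lands in the above-median group and a warning is issued.
#'
#' @param severity integer severity scores (cases; NAs allowed and ignored
#'   for the threshold, propagated in the output).
#' @return integer vector of 0/1 indicators with attribute `"threshold"`.
#' @examples
#' severitySplit(c(1, 2, 3, 4, 5))   # threshold 3 -> 0 0 1 1 1
#' @export
severitySplit <- function(severity) {
  ok <- !is.na(severity)
  if (!any(ok))
    .err("no case severity scores to split", "grsEmptyGroupError")
  thr <- median(severity[ok])
  if (diff(range(severity[ok])) == 0)
    warning("all severity scores equal: degenerate split, everyone 'above median'")
  out <- ifelse(ok, as.integer(severity >= thr), NA_integer_)
  attr(out, "threshold") <- thr
  out
}

#' Add the inverse-normalized BMI to a cohort
#'
#' Computes [inverseNormalTransform()] of `bmi_raw` over the full sample once
#' (a single pre-analysis transformation) and stores it as `bmi_int`; also
#' adds the severity median-split indicator `severity_high` when severity
#' scores are present.
#'
#' @param x a [GrsCohort-class] whose phenotypes include `bmi_raw`.
#' @param offset passed to [inverseNormalTransform()].
#' @return `x` with `bmi_int` (and possibly `severity_high`) added.
#' @export
addTransformedBmi <- function(x, offset = 3/8) {
  stopifnot(is(x, "GrsCohort"))
  cd <- colData(x)
  if (!"bmi_raw" %in% colnames(cd))
    .err("phenotypes must contain 'bmi_raw'", "grsInvalidSpecError")
  colData(x)$bmi_int <- inverseNormalTransform(cd$bmi_raw, offset = offset)
  if ("severity" %in% colnames(cd) && any(!is.na(cd$severity)))
    colData(x)$severity_high <- as.integer(severitySplit(cd$severity))
  x
}
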