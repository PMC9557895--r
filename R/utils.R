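# Internal helpers: typed conditions and the shared least-squares engine.

.err <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "grsInteractError", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    .err(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)),
         "grsInvalidConfigError")
  x
}

# Least-squares fit via QR with rank check; SEs from R^{-1}R^{-T}.
# Two-sided P from the normal approximation when residual df >= 200,
# otherwise the exact t distribution.
.ols <- function(X, y, exactTDf = 200L) {
  keep <- is.finite(y) & rowSums(!is.finite(X)) == 0L
  if (!all(keep)) {
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p)
    .err(sprintf("only %d observations for %d model terms", n, p),
         "grsInsufficientDataError")
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    .err(sprintf("design matrix is rank deficient; aliased columns: %s",
                 paste(bad, collapse = ", ")),
         "grsCollinearError", columns = bad)
  }
  beta <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  df <- n - p
  s2 <- sum(res^2) / df
  R <- qr.R(qrx)
  piv <- qrx$pivot
  Rinv <- backsolve(R, diag(p))
  xtxinv <- tcrossprod(Rinv)
  vc <- matrix(NA_real_, p, p)
  vc[piv, piv] <- xtxinv
  se <- sqrt(diag(vc) * s2)
  tstat <- beta / se
  pval <- if (df >= exactTDf) 2 * pnorm(-abs(tstat)) else 2 * pt(-abs(tstat), df)
  list(coefficients = data.frame(term = colnames(X),
                                 estimate = unname(beta),
                                 se = unname(se),
                                 statistic = unname(tstat),
                                 p = unname(pval),
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       df = df, sigma2 = s2, n = n)
}

# Covariate design matrix without intercept; categorical columns expand to
# indicators with the most frequent level as reference.
.covariateMatrix <- function(data, covariates) {
  if (length(covariates) == 0L)
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0L))
  missing <- setdiff(covariates, names(data))
  if (length(missing))
    .err(sprintf("covariate column(s) not found: %s",
                 paste(missing, collapse = ", ")),
         "grsInvalidSpecError")
  df <- data[covariates]
  for (nm in covariates) {
    v <- df[[nm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      tab <- table(v)
      v <- stats::relevel(droplevels(v), ref = names(tab)[which.max(tab)])
    }
    df[[nm]] <- v
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1L, drop = FALSE]
}

.formatP <- function(p) formatC(p, format = "e", digits = 3)
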