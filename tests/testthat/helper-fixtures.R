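# Shared fixtures and independent oracles, built in code at test time.

# Independent ordinary-least-squares oracle: explicit normal equations.
olsOracle <- function(X, y) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  beta <- as.vector(XtXinv %*% t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtXinv) * s2)
  t <- beta / se
  p <- if (df >= 200) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df)
  list(beta = setNames(beta, colnames(X)), se = setNames(se, colnames(X)),
       p = setNames(p, colnames(X)), df = df)
}

# Small deterministic weight table.
toyWeights <- function(w, eaf = rep(0.5, length(w))) {
  data.frame(variant_id = sprintf("v%d", seq_along(w)),
             effect_allele = rep(c("A", "C"), length.out = length(w)),
             other_allele = rep(c("G", "T"), length.out = length(w)),
             weight = w, eaf = eaf, stringsAsFactors = FALSE)
}

toyDosages <- function(mat, variants = sprintf("v%d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(sprintf("i%03d", seq_len(nrow(mat))), variants)
  mat
}

# Small analysis frame with a genetic term, binary exposure and covariates.
modelFixture <- function(n = 30, seed = 1, betaInt = 0) {
  set.seed(seed)
  g <- rnorm(n, 10, 2)
  E <- rbinom(n, 1, 0.5)
  age <- runif(n, 40, 70)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.2 * g + 0.5 * E + betaInt * g * E + 0.01 * age + rnorm(n)
  data.frame(bmi_int = y, bmi_raw = 27 + 4 * y, grs = g, case = E,
             age = age, sex = sex)
}

colDataFrame <- function(cohort) {
  as.data.frame(SummarizedExperiment::colData(cohort))
}
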