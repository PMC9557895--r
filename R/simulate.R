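#' Synthetic cohort configuration
#'
#' Defines the generative model for a synthetic cohort with the structure the
#' interaction analysis assumes: independent biallelic variants under
#' Hardy-Weinberg equilibrium, BMI linear in the weighted allele score on
#' either an additive (homoscedastic) or multiplicative (lognormal,
#' mean-variance coupled) scale, a binary exposure whose probability is a
#' function of BMI calibrated so exposed cases have a higher BMI mean and SD
#' than controls, an integer severity score with a BMI-correlated mean among
#' cases, a treated flag within cases, and covariates (age, sex, centre, TDI,
#' five PCs, genotyping array) independent of genotype and exposure unless a
#' confounding switch is set.
#'
#' The defaults mirror the moment structure of a large population cohort with
#' depression phenotypes: BMI 27 (4.5) kg/m^2, exposure prevalence 0.24 with
#' cases 0.6 kg/m^2 heavier and SD inflated by 1.16, and 73 variants whose
#' weights give the score a realistic ~2-3% share of outcome variance.
#'
#' @param n_individuals,n_variants cohort and panel sizes.
#' @param allele_freq_range interval for effect-allele frequencies, strictly
#'   inside (0, 1); a zero-width interval fixes the frequency.
#' @param weight_scale mean per-allele effect in inverse-normal (SD) units of
#'   BMI; 0 gives a genetics-free null outcome.
#' @param bmi_mean,bmi_sd marginal BMI moments (kg/m^2).
#' @param noise_model `"additive_normal"` (homoscedastic) or
#'   `"multiplicative_lognormal"` (raw-scale variance grows with the mean).
#' @param exposure_prevalence case proportion.
#' @param exposure_bmi_shift target case-minus-control BMI mean difference
#'   (kg/m^2).
#' @param exposure_bmi_scale target case/control BMI SD ratio (>= 1 for the
#'   artefact-generating direction).
#' @param true_interaction per-allele-by-exposure coefficient on the
#'   inverse-normal BMI scale (0 = no real interaction).
#' @param treated_fraction_in_cases probability a case is on treatment.
#' @param severity_max maximum of the integer severity score (cases only).
#' @param confound_age_exposure,confound_tdi_bmi optional confounding
#'   switches (0 = off): log-odds of case status per 15 years of age, and BMI
#'   kg/m^2 per TDI unit.
#' @param seed integer master seed; all sub-streams derive from it.
#'
#' @return A validated list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(n_individuals = 1000, n_variants = 20, seed = 7)
#' @export
simConfig <- function(n_individuals = 10000L,
                      n_variants = 73L,
                      allele_freq_range = c(0.05, 0.95),
                      weight_scale = 0.03,
                      bmi_mean = 27,
                      bmi_sd = 4.5,
                      noise_model = c("additive_normal",
                                      "multiplicative_lognormal"),
                      exposure_prevalence = 0.24,
                      exposure_bmi_shift = 0.6,
                      exposure_bmi_scale = 1.16,
                      true_interaction = 0,
                      treated_fraction_in_cases = 0.5,
                      severity_max = 8L,
                      confound_age_exposure = 0,
                      confound_tdi_bmi = 0,
                      seed = 42L) {
  noise_model <- match.arg(noise_model)
  .assertNumber(n_individuals, "n_individuals", lower = 1)
  .assertNumber(n_variants, "n_variants", lower = 1)
  if (!is.numeric(allele_freq_range) || length(allele_freq_range) != 2L ||
      any(!is.finite(allele_freq_range)) ||
      allele_freq_range[1L] > allele_freq_range[2L] ||
      allele_freq_range[1L] <= 0 || allele_freq_range[2L] >= 1)
    .err("allele_freq_range must be an ordered interval strictly inside (0, 1)",
         "grsInvalidConfigError")
  .assertNumber(weight_scale, "weight_scale", lower = 0)
  .assertNumber(bmi_mean, "bmi_mean", lower = 1)
  .assertNumber(bmi_sd, "bmi_sd", lower = 1e-6)
  .assertNumber(exposure_prevalence, "exposure_prevalence", 0, 1)
  .assertNumber(exposure_bmi_shift, "exposure_bmi_shift")
  .assertNumber(exposure_bmi_scale, "exposure_bmi_scale", lower = 0)
  .assertNumber(true_interaction, "true_interaction")
  .assertNumber(treated_fraction_in_cases, "treated_fraction_in_cases", 0, 1)
  .assertNumber(severity_max, "severity_max", lower = 1)
  .assertNumber(seed, "seed", lower = 0, upper = 2^30)
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_variants = as.integer(n_variants),
              allele_freq_range = allele_freq_range,
              weight_scale = weight_scale,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              noise_model = noise_model,
              exposure_prevalence = exposure_prevalence,
              exposure_bmi_shift = exposure_bmi_shift,
              exposure_bmi_scale = exposure_bmi_scale,
              true_interaction = true_interaction,
              treated_fraction_in_cases = treated_fraction_in_cases,
              severity_max = as.integer(severity_max),
              confound_age_exposure = confound_age_exposure,
              confound_tdi_bmi = confound_tdi_bmi,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d individuals, %d variants, %s noise, seed %d\n",
              x$n_individuals, x$n_variants, x$noise_model, x$seed))
  cat(sprintf("  BMI %g (%g); exposure prev %.2f, shift %+.2f, SD ratio %.2f; gamma = %g\n",
              x$bmi_mean, x$bmi_sd, x$exposure_prevalence,
              x$exposure_bmi_shift, x$exposure_bmi_scale, x$true_interaction))
  invisible(x)
}

.alleles <- c("A", "C", "G", "T")

#' Simulate a variant panel and Hardy-Weinberg dosages
#'
#' Effect-allele frequencies are drawn uniformly from
#' `allele_freq_range`; dosages are the count of effect alleles,
#' `Binomial(2, f)` per variant; per-allele weights are positive (the panel
#' is oriented to the trait-increasing allele) with magnitudes uniform in
#' `weight_scale * [0.3, 1.7]`.
#'
#' @param config a [simConfig()] object.
#' @return list with `weights` (data.frame: variant_id, effect_allele,
#'   other_allele, weight, eaf) and `dosages` (individuals x variants matrix).
#' @examples
#' sim <- simulateVariants(simConfig(n_individuals = 100, n_variants = 5))
#' @export
simulateVariants <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  M <- config$n_variants
  n <- config$n_individuals
  rng <- config$allele_freq_range
  f <- runif(M, rng[1L], rng[2L])
  # weight_scale = 0 is the genetics-free null: the panel keeps nominal
  # discovery-scale weights (so scoring still works) but simulateBmi()
  # ignores them
  wScale <- if (config$weight_scale > 0) config$weight_scale else 0.03
  w <- wScale * runif(M, 0.3, 1.7)
  ea <- sample(.alleles, M, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(.alleles, a), 1L), character(1))
  ids <- sprintf("snp_%03d", seq_len(M))
  dos <- matrix(rbinom(n * M, 2L, rep(f, each = n)), nrow = n, ncol = M,
                dimnames = list(sprintf("ind_%05d", seq_len(n)), ids))
  list(weights = data.frame(variant_id = ids, effect_allele = ea,
                            other_allele = unname(oa), weight = w, eaf = f,
                            stringsAsFactors = FALSE),
       dosages = dos)
}

#' Simulate raw BMI from dosages and weights
#'
#' The centered weighted score `g = sum_j w_j (d_j - 2 f_j)` is on the
#' inverse-normal (SD) scale.  Under `additive_normal`,
#' `BMI = bmi_mean + bmi_sd * (g + e)` with homoscedastic Gaussian `e` scaled
#' so the marginal SD is about `bmi_sd`.  Under `multiplicative_lognormal`,
#' log BMI is linear in the standardized `g + e`, with the log-scale SD set
#' from the coefficient of variation `bmi_sd / bmi_mean`, so the raw-scale
#' conditional variance grows with the conditional mean — the mean-variance
#' coupling that manufactures spurious raw-scale interactions.
#'
#' @param dosages individuals x variants matrix (increasing-allele oriented).
#' @param weights weight table as from [simulateVariants()].
#' @param config a [simConfig()] object.
#' @return numeric vector of raw BMI (kg/m^2).
#' @export
simulateBmi <- function(dosages, weights, config) {
  stopifnot(inherits(config, "SimConfig"))
  if (ncol(dosages) != nrow(weights))
    .err("dosage columns and weight rows must match", "grsInvalidConfigError")
  if (!config$noise_model %in% c("additive_normal", "multiplicative_lognormal"))
    .err(sprintf("unknown noise_model '%s'", config$noise_model),
         "grsInvalidConfigError")
  set.seed(config$seed + 1L)
  n <- nrow(dosages)
  w <- weights$weight
  f <- weights$eaf
  if (config$weight_scale > 0) {
    g <- as.vector(dosages %*% w) - sum(2 * f * w)
    vg <- sum(w^2 * 2 * f * (1 - f))
  } else {
    g <- numeric(n)
    vg <- 0
  }
  se <- sqrt(max(1 - vg, 0.05))
  z <- g + rnorm(n, 0, se)
  if (config$noise_model == "additive_normal") {
    bmi <- config$bmi_mean + config$bmi_sd * z
  } else {
    cv <- config$bmi_sd / config$bmi_mean
    s <- sqrt(log1p(cv^2))
    mu <- log(config$bmi_mean) - s^2 / 2
    bmi <- exp(mu + s * z / sqrt(vg + se^2))
  }
  pmax(bmi, 5)
}

# Case-selection probability p(b) = plogis(a + c z + d z^2), z standardized
# BMI.  Target case moments follow from (prevalence, shift, scale) and the
# marginal moments: case mean = m + (1-pi)*shift, and case/control variances
# split the marginal variance so their SD ratio equals `scale`.  The
# quadratic-logistic form is exact for a two-component normal mixture; its
# coefficients seed a numerical polish against the EMPIRICAL bmi sample so
# the realized group moments hit the targets even though the marginal is not
# literally that mixture.
.calibrateSelection <- function(bmi, pi1, shift, scale) {
  n <- length(bmi)
  if (shift == 0 && scale == 1) return(rep(pi1, n))
  m <- mean(bmi); v <- var(bmi); sdev <- sqrt(v)
  c2 <- scale^2
  mu1 <- m + (1 - pi1) * shift
  mu0 <- mu1 - shift
  Q <- v + m^2 - pi1 * mu1^2 - (1 - pi1) * mu0^2
  v0 <- Q / (pi1 * c2 + (1 - pi1))
  if (v0 <= 0)
    .err("exposure shift/scale incompatible with the marginal BMI variance",
         "grsInvalidConfigError")
  v1 <- c2 * v0
  s1 <- sqrt(v1)
  z <- (bmi - m) / sdev
  # mixture-posterior log odds, expanded in z, as the starting point
  a0 <- qlogis(pi1) + log(sqrt(v0 / v1)) -
    (m - mu1)^2 / (2 * v1) + (m - mu0)^2 / (2 * v0)
  c0 <- sdev * ((mu1 - m) / v1 - (mu0 - m) / v0)
  d0 <- v * (1 / v0 - 1 / v1) / 2
  obj <- function(par) {
    p <- plogis(par[1L] + par[2L] * z + par[3L] * z^2)
    sp <- sum(p)
    cm <- sum(p * bmi) / sp
    cs <- sqrt(sum(p * (bmi - cm)^2) / sp)
    (sp / n - pi1)^2 / pi1^2 + ((cm - mu1) / sdev)^2 + ((cs - s1) / sdev)^2
  }
  fit <- stats::optim(c(a0, c0, d0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  par <- fit$par
  plogis(par[1L] + par[2L] * z + par[3L] * z^2)
}

#' Assign exposure status, severity and treatment conditional on BMI
#'
#' Case probability is a logistic-quadratic function of standardized BMI
#' (the exact form of a two-component normal-mixture posterior), with
#' coefficients calibrated numerically so that, under the observed BMI
#' sample, the expected prevalence, case mean and case SD hit the targets
#' implied by `exposure_prevalence`, `exposure_bmi_shift` and
#' `exposure_bmi_scale`; sampling case status from it reproduces the target
#' group moments up to sampling noise (selection on the outcome, as in real
#' case ascertainment).  Severity (cases only) is
#' `Binomial(severity_max, p)` with `p` increasing in within-case
#' standardized BMI, so a severity median split shows a BMI gradient.  The
#' treated flag is Bernoulli within cases and NA for controls.
#'
#' @param bmi numeric vector of raw BMI.
#' @param config a [simConfig()] object.
#' @param age optional age vector, used only when `confound_age_exposure != 0`.
#' @return data.frame with columns `case`, `severity`, `treated`.
#' @export
assignExposures <- function(bmi, config, age = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (any(!is.finite(bmi)))
    .err("bmi must be finite", "grsInvalidConfigError")
  set.seed(config$seed + 2L)
  n <- length(bmi)
  pi1 <- config$exposure_prevalence
  s <- config$exposure_bmi_shift
  c2 <- config$exposure_bmi_scale^2
  p <- .calibrateSelection(bmi, pi1, s, config$exposure_bmi_scale)
  if (config$confound_age_exposure != 0 && !is.null(age)) {
    eta <- qlogis(pmin(pmax(p, 1e-10), 1 - 1e-10)) +
      config$confound_age_exposure * (age - 55) / 15
    p <- plogis(eta)
  }
  case <- rbinom(n, 1L, p)
  severity <- rep(NA_integer_, n)
  idx <- which(case == 1L)
  if (length(idx)) {
    zb <- (bmi[idx] - mean(bmi[idx])) / max(sd(bmi[idx]), 1e-8)
    severity[idx] <- rbinom(length(idx), config$severity_max,
                            plogis(qlogis(0.4) + 0.35 * zb))
  }
  treated <- rep(NA_integer_, n)
  if (length(idx))
    treated[idx] <- rbinom(length(idx), 1L, config$treated_fraction_in_cases)
  data.frame(case = case, severity = severity, treated = treated)
}

#' Generate a full synthetic cohort
#'
#' Orchestrates [simulateVariants()], [simulateBmi()], covariate generation
#' and [assignExposures()], then applies any planted interaction:
#' `bmi <- bmi + bmi_sd * true_interaction * case * (G - E[G])` with `G` the
#' allele-count-scale weighted score, i.e. a per-allele-by-exposure effect of
#' `true_interaction` on the inverse-normal scale, on the same genetic scale
#' the interaction model tests.  Covariates (age U(40, 70), sex Bernoulli(0.5),
#' centre 1 of 6, TDI N(0, 3), PC1-5 N(0, 1), array Bernoulli(0.5)) are
#' independent of genotype and exposure unless confounding switches are set.
#'
#' @param config a [simConfig()] object.
#' @return A [GrsCohort-class]; phenotypes hold `bmi_raw`, `case`,
#'   `severity`, `treated` and covariates.  Identical config (including seed)
#'   gives an identical cohort.
#' @examples
#' cohort <- simulateCohort(simConfig(n_individuals = 500, n_variants = 10))
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  sim <- simulateVariants(config)
  bmi <- simulateBmi(sim$dosages, sim$weights, config)
  n <- config$n_individuals
  set.seed(config$seed + 3L)
  cov <- data.frame(age = runif(n, 40, 70),
                    sex = rbinom(n, 1L, 0.5),
                    centre = sample(sprintf("C%d", 1:6), n, replace = TRUE),
                    tdi = rnorm(n, 0, 3),
                    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
                    pc4 = rnorm(n), pc5 = rnorm(n),
                    array = rbinom(n, 1L, 0.5),
                    stringsAsFactors = FALSE)
  if (config$confound_tdi_bmi != 0)
    bmi <- pmax(bmi + config$confound_tdi_bmi * cov$tdi, 5)
  expo <- assignExposures(bmi, config, age = cov$age)
  if (config$true_interaction != 0) {
    # per-allele effect on the allele-count-scale GRS, the same scale the
    # interaction model's genetic term uses
    w <- sim$weights$weight
    gsc <- as.vector(sim$dosages %*% w) * length(w) / sum(w)
    egsc <- 2 * sum(sim$weights$eaf * w) * length(w) / sum(w)
    bmi <- bmi + config$bmi_sd * config$true_interaction *
      expo$case * (gsc - egsc)
  }
  pheno <- cbind(data.frame(bmi_raw = bmi), expo, cov)
  GrsCohort(sim$dosages, sim$weights, pheno)
}
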