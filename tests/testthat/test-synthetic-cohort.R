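# Synthetic cohort generator: shapes, determinism, Hardy-Weinberg dosages,
# outcome construction and exposure-moment calibration.

test_that("variant panel has the requested shape and HWE dosage means", {
  cfg <- simConfig(n_individuals = 2000, n_variants = 73, seed = 1)
  sim <- simulateVariants(cfg)
  expect_equal(nrow(sim$weights), 73)
  expect_equal(dim(sim$dosages), c(2000, 73))
  expect_true(all(sim$dosages %in% 0:2))
  expect_true(all(sim$weights$weight > 0))
  # per-variant mean within a Bonferroni-adjusted normal bound of 2f
  se <- sqrt(2 * sim$weights$eaf * (1 - sim$weights$eaf) / 2000)
  z <- qnorm(1 - 0.0013 / 73)
  expect_true(all(abs(colMeans(sim$dosages) - 2 * sim$weights$eaf) < z * se))
  # and per-variant at 3 SE on a small panel
  sim2 <- simulateVariants(simConfig(n_individuals = 5000, n_variants = 5,
                                     seed = 14))
  se2 <- sqrt(2 * sim2$weights$eaf * (1 - sim2$weights$eaf) / 5000)
  expect_true(all(abs(colMeans(sim2$dosages) - 2 * sim2$weights$eaf) < 3 * se2))
})

test_that("zero-width frequency interval fixes the allele frequency", {
  cfg <- simConfig(n_individuals = 3000, n_variants = 5, seed = 2,
                   allele_freq_range = c(0.5, 0.5))
  sim <- simulateVariants(cfg)
  se3 <- 3 * sqrt(2 * 0.25 / 3000)
  expect_true(all(abs(colMeans(sim$dosages) - 1) < se3))
})

test_that("identical config and seed give an identical cohort", {
  cfg <- simConfig(n_individuals = 300, n_variants = 8, seed = 9)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(dosageMatrix(a), dosageMatrix(b))
  expect_identical(colDataFrame(a), colDataFrame(b))
  expect_identical(variantWeights(a), variantWeights(b))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(allele_freq_range = c(0.9, 0.1)),
               class = "grsInvalidConfigError")
  expect_error(simConfig(allele_freq_range = c(0, 0.5)),
               class = "grsInvalidConfigError")
  expect_error(simConfig(exposure_prevalence = 1.5),
               class = "grsInvalidConfigError")
  cfg <- simConfig(n_individuals = 50, n_variants = 3)
  bad <- cfg
  bad$noise_model <- "cauchy"
  sim <- simulateVariants(cfg)
  expect_error(simulateBmi(sim$dosages, sim$weights, bad),
               class = "grsInvalidConfigError")
})

test_that("weight_scale = 0 decouples BMI from genotype", {
  cfg <- simConfig(n_individuals = 5000, n_variants = 10, seed = 3,
                   weight_scale = 0, exposure_bmi_shift = 0,
                   exposure_bmi_scale = 1)
  ch <- computeGrs(simulateCohort(cfg))
  cd <- colDataFrame(ch)
  fit <- lm(bmi_raw ~ grs, data = cd)
  expect_lt(abs(coef(fit)["grs"]), 3 * summary(fit)$coefficients["grs", 2])
})

test_that("additive mode is homoscedastic with the requested mean", {
  cfg <- simConfig(n_individuals = 50000, n_variants = 10, seed = 4)
  sim <- simulateVariants(cfg)
  bmi <- simulateBmi(sim$dosages, sim$weights, cfg)
  expect_lt(abs(mean(bmi) - cfg$bmi_mean), 3 * cfg$bmi_sd / sqrt(50000))
})

test_that("multiplicative mode couples conditional SD to the mean", {
  cfg <- simConfig(n_individuals = 20000, n_variants = 10, seed = 5,
                   noise_model = "multiplicative_lognormal",
                   exposure_bmi_shift = 0, exposure_bmi_scale = 1)
  ch <- computeGrs(simulateCohort(cfg))
  cd <- colDataFrame(ch)
  expect_gt(sd(cd$bmi_raw[cd$grs_decile == 10]),
            sd(cd$bmi_raw[cd$grs_decile == 1]))
})

test_that("null exposure settings give matched group distributions", {
  cfg <- simConfig(n_individuals = 20000, n_variants = 10, seed = 6,
                   exposure_bmi_shift = 0, exposure_bmi_scale = 1,
                   treated_fraction_in_cases = 0)
  ch <- simulateCohort(cfg)
  cd <- colDataFrame(ch)
  diff <- mean(cd$bmi_raw[cd$case == 1]) - mean(cd$bmi_raw[cd$case == 0])
  se <- sqrt(var(cd$bmi_raw) * (1 / sum(cd$case == 1) + 1 / sum(cd$case == 0)))
  expect_lt(abs(diff), 3 * se)
  expect_identical(sum(cd$treated, na.rm = TRUE), 0L)
  expect_true(all(is.na(cd$severity[cd$case == 0])))
  expect_true(all(!is.na(cd$severity[cd$case == 1])))
})

test_that("exposure-moment calibration hits the target shift and SD ratio", {
  cfg <- simConfig(n_individuals = 100000, n_variants = 8, seed = 7,
                   exposure_bmi_shift = 0.7, exposure_bmi_scale = 1.15)
  ch <- simulateCohort(cfg)
  cd <- colDataFrame(ch)
  shift <- mean(cd$bmi_raw[cd$case == 1]) - mean(cd$bmi_raw[cd$case == 0])
  ratio <- sd(cd$bmi_raw[cd$case == 1]) / sd(cd$bmi_raw[cd$case == 0])
  expect_lt(abs(shift - 0.7), 0.1)
  expect_lt(abs(ratio - 1.15), 0.05)
  expect_lt(abs(mean(cd$case) - cfg$exposure_prevalence), 0.02)
})

test_that("covariates are independent of the GRS by default", {
  cfg <- simConfig(n_individuals = 8000, n_variants = 10, seed = 8)
  ch <- computeGrs(simulateCohort(cfg))
  cd <- colDataFrame(ch)
  se3 <- 3 / sqrt(nrow(cd))
  for (v in c("age", "tdi", "pc1", "pc2", "sex"))
    expect_lt(abs(cor(cd$grs, cd[[v]])), se3)
})

test_that("severity carries a BMI gradient among cases", {
  cfg <- simConfig(n_individuals = 20000, n_variants = 8, seed = 10)
  ch <- simulateCohort(cfg)
  cd <- colDataFrame(ch)
  cases <- cd[cd$case == 1, ]
  hi <- severitySplit(cases$severity) == 1
  d <- mean(cases$bmi_raw[hi]) - mean(cases$bmi_raw[!hi])
  se <- sqrt(var(cases$bmi_raw) * (1 / sum(hi) + 1 / sum(!hi)))
  expect_gt(d, 3 * se)
})
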