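# Interaction and stratified linear models against an independent
# normal-equations oracle, decile contrasts, the per-variant scan and unit
# conversion.

test_that("interaction fit matches the normal-equations oracle on small fixtures", {
  for (seed in 1:3) {
    dat <- modelFixture(n = 12 + 8 * seed, seed = seed, betaInt = 0.1)
    fit <- fitInteractionModel(dat, covariates = c("age", "sex"))
    X <- cbind(`(Intercept)` = 1, g = dat$grs, E = dat$case,
               `g:E` = dat$grs * dat$case, age = dat$age, sex = dat$sex)
    oracle <- olsOracle(X, dat$bmi_int)
    expect_equal(fit@betaInt, unname(oracle$beta["g:E"]), tolerance = 1e-8)
    expect_equal(fit@seInt, unname(oracle$se["g:E"]), tolerance = 1e-8)
    expect_equal(fit@pInt, unname(oracle$p["g:E"]), tolerance = 1e-8)
  }
})

test_that("stratified fits match the oracle within each exposure level", {
  dat <- modelFixture(n = 40, seed = 4)
  st <- fitStratifiedAssociation(dat, covariates = "age")
  for (lv in 0:1) {
    sub <- dat[dat$case == lv, ]
    X <- cbind(`(Intercept)` = 1, g = sub$grs, age = sub$age)
    oracle <- olsOracle(X, sub$bmi_int)
    row <- st[st$stratum == sprintf("case=%d", lv), ]
    expect_equal(row$beta, unname(oracle$beta["g"]), tolerance = 1e-8)
    expect_equal(row$se, unname(oracle$se["g"]), tolerance = 1e-8)
    expect_equal(row$n, nrow(sub))
  }
  expect_equal(sum(st$n), nrow(dat))
})

test_that("categorical covariates expand with the modal reference level", {
  set.seed(5)
  dat <- modelFixture(n = 60, seed = 5)
  dat$centre <- sample(c("C1", "C2", "C3"), 60, replace = TRUE,
                       prob = c(0.2, 0.5, 0.3))
  fit <- fitInteractionModel(dat, covariates = c("age", "centre"))
  # oracle with explicit indicators, C2 (modal) as reference
  X <- cbind(`(Intercept)` = 1, g = dat$grs, E = dat$case,
             `g:E` = dat$grs * dat$case, age = dat$age,
             C1 = as.numeric(dat$centre == "C1"),
             C3 = as.numeric(dat$centre == "C3"))
  oracle <- olsOracle(X, dat$bmi_int)
  expect_equal(fit@betaInt, unname(oracle$beta["g:E"]), tolerance = 1e-8)
  expect_equal(fit@seInt, unname(oracle$se["g:E"]), tolerance = 1e-8)
})

test_that("null cohorts give stratum betas near zero", {
  cfg <- simConfig(n_individuals = 4000, n_variants = 10, seed = 6,
                   weight_scale = 0, exposure_bmi_shift = 0,
                   exposure_bmi_scale = 1)
  ch <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
  st <- fitStratifiedAssociation(ch)
  expect_true(all(abs(st$beta) < 3 * st$se))
})

test_that("Keller adjustment is a no-op without covariates and unbiased with them", {
  dat <- modelFixture(n = 50, seed = 7)
  base <- fitInteractionModel(dat)
  kel <- fitInteractionModel(dat, keller = TRUE)
  expect_identical(base@betaInt, kel@betaInt)
  # with independent covariates the two estimates agree within half an SE
  # on average across simulated null cohorts
  diffs <- vapply(1:40, function(i) {
    cfg <- simConfig(n_individuals = 800, n_variants = 8, seed = 100 + i,
                     exposure_bmi_shift = 0, exposure_bmi_scale = 1)
    ch <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
    b <- fitInteractionModel(ch, covariates = c("age", "sex", "tdi"))
    k <- fitInteractionModel(ch, covariates = c("age", "sex", "tdi"),
                             keller = TRUE)
    c(abs(b@betaInt - k@betaInt), b@seInt)
  }, numeric(2))
  expect_lt(mean(diffs[1, ]), 0.5 * mean(diffs[2, ]))
})

test_that("constant exposure and rank deficiency raise typed errors", {
  dat <- modelFixture(n = 30, seed = 8)
  dat$case <- 1
  expect_error(fitInteractionModel(dat), class = "grsInvalidSpecError")
  expect_error(fitStratifiedAssociation(dat), class = "grsEmptyGroupError")
  dat2 <- modelFixture(n = 30, seed = 9)
  dat2$age2 <- dat2$age
  err <- tryCatch(fitInteractionModel(dat2, covariates = c("age", "age2")),
                  grsCollinearError = function(e) e)
  expect_s3_class(err, "grsCollinearError")
  expect_match(conditionMessage(err), "age2")
})

test_that("decile contrasts recover a constant exposure shift exactly", {
  set.seed(10)
  n <- 400
  dat <- data.frame(grs_decile = rep(1:10, each = n / 10),
                    case = rep(c(0, 1), n / 2))
  dat$bmi_raw <- 26 + 0.3 * dat$grs_decile + 1.0 * dat$case
  dc <- decileContrast(dat)
  expect_equal(unname(dc), c(1, 1))
  # empty cell error
  dat2 <- dat[!(dat$grs_decile == 1 & dat$case == 1), ]
  expect_error(decileContrast(dat2), class = "grsEmptyCellError")
})

test_that("a planted interaction widens the top-decile contrast", {
  hits <- vapply(1:15, function(i) {
    cfg <- simConfig(n_individuals = 8000, n_variants = 10, seed = 200 + i,
                     exposure_bmi_shift = 0, exposure_bmi_scale = 1,
                     true_interaction = 0.12)
    ch <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
    dc <- decileContrast(colDataFrame(ch))
    dc["top"] > dc["bottom"]
  }, logical(1))
  expect_gte(sum(hits), 13)
})

test_that("the per-variant scan returns one row per variant with a Bonferroni flag", {
  cfg <- simConfig(n_individuals = 500, n_variants = 73, seed = 11)
  ch <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
  scan <- perSnpInteractionScan(ch)
  expect_equal(nrow(scan), 73)
  expect_equal(attr(scan, "bonferroni_threshold"), 0.05 / 73)
  expect_false(any(scan$skipped))
})

test_that("monomorphic variants are skipped and a planted variant is flagged", {
  set.seed(12)
  n <- 50000
  w <- toyWeights(rep(0.1, 5), eaf = rep(0.5, 5))
  d <- toyDosages(matrix(rbinom(5 * n, 2, 0.5), n, 5))
  d[, 3] <- 0   # monomorphic
  E <- rbinom(n, 1, 0.5)
  y <- 0.02 * d[, 1] + 0.08 * d[, 1] * E + rnorm(n)
  ch <- GrsCohort(d, w, data.frame(bmi_int = y, bmi_raw = 27 + 4 * y,
                                   case = E))
  expect_warning(scan <- perSnpInteractionScan(ch), "monomorphic")
  expect_true(scan$skipped[3])
  expect_true(is.na(scan$p_int[3]))
  flagged <- scan$variant_id[scan$bonferroni]
  expect_identical(flagged, "v1")
})

test_that("per-allele betas convert to kilograms via SD and height", {
  expect_equal(betaToWeightChange(0, bmiSdRaw = 4.6), 0)
  expect_equal(betaToWeightChange(1, nAlleles = 1, heightM = 1.73,
                                  bmiSdRaw = 1), 2.9929)
  expect_equal(betaToWeightChange(0.0255, nAlleles = 10, heightM = 1.73,
                                  bmiSdRaw = 4.6), 3.5107, tolerance = 1e-4)
})
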