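# Matched-group selection, the negative-control replicate engine and its
# summary statistics.

test_that("selection converges when targets equal the pool moments", {
  set.seed(1)
  pool <- rnorm(400, 27, 4.5)
  idx <- selectMatchedGroup(pool, 200, mean(pool), sd(pool), seed = 2)
  expect_length(idx, 200)
  expect_lt(abs(mean(pool[idx]) - mean(pool)), 0.05)
  expect_lt(abs(sd(pool[idx]) - sd(pool)), 0.05)
})

test_that("impossible targets raise an infeasibility error with best moments", {
  set.seed(2)
  pool <- rnorm(100, 27, 4)
  expect_error(selectMatchedGroup(pool, 50, max(pool) + 10, 4, seed = 1),
               class = "grsInfeasibleError")
  err <- tryCatch(
    selectMatchedGroup(pool, 50, 27, 0.001, tolerance = 1e-4, seed = 1,
                       maxIter = 2000),
    grsInfeasibleError = function(e) e)
  expect_s3_class(err, "grsInfeasibleError")
  expect_true(is.finite(err$mean))
})

test_that("selection matches a planted subpopulation, verified by brute force", {
  set.seed(3)
  pool <- c(rnorm(100, 24, 2), rnorm(100, 31, 3))
  idx <- selectMatchedGroup(pool, 60, 31, 3, seed = 4)
  expect_lt(abs(mean(pool[idx]) - 31), 0.05)
  expect_lt(abs(sd(pool[idx]) - 3), 0.05)
  # miniature: exhaustive search over all 20-choose-5 subsets, with a
  # planted 5-subset whose exact moments are the target
  set.seed(5)
  planted <- rnorm(5, 30, 2)
  mini <- c(rnorm(15, 24, 1.5), planted)
  tm <- mean(planted); ts <- sd(planted)
  combs <- combn(20, 5)
  loss <- apply(combs, 2, function(ix)
    (mean(mini[ix]) - tm)^2 + (sd(mini[ix]) - ts)^2)
  bestLoss <- min(loss)
  tol <- 0.05
  feasible <- any(apply(combs, 2, function(ix)
    abs(mean(mini[ix]) - tm) < tol && abs(sd(mini[ix]) - ts) < tol))
  expect_true(feasible)   # oracle confirms a solution exists
  idx <- selectMatchedGroup(mini, 5, tm, ts, tolerance = tol, seed = 6,
                            maxIter = 50000)
  expect_lt(abs(mean(mini[idx]) - tm), tol)
  expect_lt(abs(sd(mini[idx]) - ts), tol)
  # and the optimizer cannot beat the exhaustive optimum
  achieved <- (mean(mini[idx]) - tm)^2 + (sd(mini[idx]) - ts)^2
  expect_gte(achieved, bestLoss - 1e-12)
})

test_that("empirical P is the plain proportion with strict bounds checking", {
  expect_identical(empiricalP(0, 100), 0)
  expect_identical(empiricalP(25, 100), 0.25)
  expect_error(empiricalP(5, 0), class = "grsInvalidInputError")
  expect_error(empiricalP(11, 10), class = "grsInvalidInputError")
  expect_error(empiricalP(-1, 10), class = "grsInvalidInputError")
})

test_that("median replicate follows the lower-middle rule", {
  expect_equal(medianReplicate(c(0.1, 0.5, 0.9))$p, 0.5)
  expect_equal(medianReplicate(0.3)$p, 0.3)
  expect_equal(medianReplicate(c(0.1, 0.2, 0.3, 0.4))$p, 0.2)
  m <- medianReplicate(c(0.4, 0.1, 0.3, 0.2))
  expect_equal(m$p, 0.2)
  expect_equal(m$index, 4L)
  expect_error(medianReplicate(c(NA_real_, NA_real_)),
               class = "grsEmptyGroupError")
})

test_that("replicates are disjoint, exactly sized, moment-matched and deterministic", {
  cfg <- simConfig(n_individuals = 600, n_variants = 8, seed = 20)
  ch <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
  cd <- colDataFrame(ch)
  n1 <- sum(cd$case == 1); n2 <- sum(cd$case == 0)
  neg <- runNegativeExperiments(ch, R = 8, seed = 21)
  expect_equal(neg@R, 8L)
  expect_equal(neg@meta$groupSizes, c(n1, n2))
  tg <- neg@meta$targets
  reps <- neg@replicates
  expect_true(all(abs(reps$mean1 - tg$mean1) < 0.05))
  expect_true(all(abs(reps$sd1 - tg$sd1) < 0.05))
  expect_true(all(abs(reps$mean2 - tg$mean2) < 0.05))
  expect_true(all(abs(reps$sd2 - tg$sd2) < 0.05))
  expect_identical(neg@countBelow, sum(reps$p < neg@observedP))
  expect_identical(neg@empiricalP, neg@countBelow / neg@R)
  neg2 <- runNegativeExperiments(ch, R = 8, seed = 21)
  expect_identical(neg@replicates, neg2@replicates)
  expect_identical(neg@observedP, neg2@observedP)
})

test_that("group selection is disjoint when sizes leave slack in the pool", {
  set.seed(22)
  pool <- rnorm(300, 27, 4)
  i1 <- selectMatchedGroup(pool, 80, 27.5, 4, seed = 23)
  i2 <- selectMatchedGroup(pool, 80, 26.5, 4, excludedIds = i1, seed = 24)
  expect_length(intersect(as.integer(i1), as.integer(i2)), 0)
  expect_length(i2, 80)
})

test_that("matched-null replicate P-values are uniform", {
  cfg <- simConfig(n_individuals = 2000, n_variants = 10, seed = 25,
                   exposure_bmi_shift = 0, exposure_bmi_scale = 1)
  ch <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
  neg <- runNegativeExperiments(ch, R = 1000, seed = 26)
  ks <- suppressWarnings(ks.test(replicatePValues(neg), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("selection failures abort once they pass half the attempt budget", {
  cfg <- simConfig(n_individuals = 300, n_variants = 5, seed = 27)
  ch <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
  cd <- colDataFrame(ch)
  hard <- list(mean1 = mean(cd$bmi_raw), sd1 = 0.2,
               mean2 = mean(cd$bmi_raw), sd2 = 0.2)
  expect_error(
    runNegativeExperiments(ch, R = 4, seed = 28, targets = hard,
                           groupSizes = c(100, 100), maxIter = 500),
    class = "grsInfeasibleError")
})

test_that("summary-statistics mode respects group sizes and calibrates type I error", {
  s <- simulateGroupsFromSummary(150, 27.2, 5.1, 250, 26.6, 4.4, R = 30,
                                 seed = 30)
  expect_equal(s@R, 30L)
  expect_equal(s@meta$groupSizes, c(150, 250))
  expect_true(all(s@replicates$converged))
  big <- simulateGroupsFromSummary(50000, 27.2, 5.1, 50000, 26.6, 4.4,
                                   R = 1, seed = 31, nVariants = 8)
  expect_lt(abs(big@replicates$mean1 - 27.2), 3 * 5.1 / sqrt(50000))
  expect_lt(abs(big@replicates$mean2 - 26.6), 3 * 4.4 / sqrt(50000))
  expect_lt(abs(big@replicates$sd1 - 5.1), 0.1)
})

test_that("histogram data covers all replicates and carries annotations", {
  cfg <- simConfig(n_individuals = 500, n_variants = 5, seed = 32)
  ch <- addTransformedBmi(computeGrs(simulateCohort(cfg)))
  neg <- runNegativeExperiments(ch, R = 12, seed = 33)
  h <- negControlHistogram(neg)
  expect_equal(sum(h$count), 12)
  expect_equal(attr(h, "observed_log10p"), -log10(neg@observedP))
  expect_equal(attr(h, "median_log10p"), -log10(neg@medianP))
})
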