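test_that("collinearity screen recovers exact and simulated correlations", {
  ph <- data.frame(ageOnset = 1:20, ageDiagnosis = 1:20 * 2 + 3,
                   durationFromOnset = rnorm(20),
                   durationFromDiagnosis = rnorm(20))
  out <- collinearityScreen(ph)
  expect_equal(out$correlations$r[1], 1.0)
  expect_setequal(out$excludedVariables,
                  c("ageDiagnosis", "durationFromDiagnosis",
                    "timeToDiagnosis"))
  set.seed(10)
  n <- 1e4
  indep <- data.frame(ageOnset = rnorm(n), ageDiagnosis = rnorm(n),
                      durationFromOnset = rnorm(n),
                      durationFromDiagnosis = rnorm(n))
  expect_lt(abs(collinearityScreen(indep)$correlations$r[1]), 0.05)
  # onset/diagnosis generated with r ~ 0.98 is recovered closely
  onset <- rnorm(n, 59.5, 12.9)
  diag <- 0.98 * onset + sqrt(1 - 0.98^2) * 12.9 * rnorm(n) + 1.2
  gen <- data.frame(ageOnset = onset, ageDiagnosis = diag,
                    durationFromOnset = rnorm(n),
                    durationFromDiagnosis = rnorm(n))
  expect_lt(abs(collinearityScreen(gen)$correlations$r[1] - 0.98), 0.01)
})

test_that("univariate tests use the fixed test-per-variable assignment", {
  set.seed(21)
  sim <- simulateCarrierPhenotypes(300, betas = c(familyHistory = log(8)))
  res <- univariateTests(sim$phenotypes, sim$carriers)
  expect_identical(res$test[res$variable == "sex"], "fisher_two_tailed")
  expect_identical(res$test[res$variable == "ageOnset"], "t_test")
  expect_identical(res$test[res$variable == "durationFromOnset"],
                   "mann_whitney_u")
  expect_lt(res$p[res$variable == "familyHistory"], 1e-4)
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
  expect_error(univariateTests(sim$phenotypes, character()), "subset")
})

test_that("the family-history table from the published cohort is extreme", {
  # 26/74 carriers vs 16/357 non-carriers with a family history
  expect_lt(fisherTwoTailed(26, 48, 16, 341), 5e-7)
})

test_that("a constant continuous variable is reported not-applicable", {
  set.seed(3)
  sim <- simulateCarrierPhenotypes(60)
  ph <- sim$phenotypes
  ph$ageOnset <- 50
  res <- univariateTests(ph, sim$carriers)
  expect_true(is.na(res$p[res$variable == "ageOnset"]))
})

test_that("predictor selection keeps p <= 0.1 including the boundary", {
  res <- data.frame(variable = c("sex", "ageOnset", "familyHistory",
                                 "siteOfOnset", "durationFromOnset"),
                    p = c(0.028, 0.018, 5e-8, 0.779, 0.144))
  expect_identical(selectPredictors(res),
                   c("sex", "ageOnset", "familyHistory"))
  expect_identical(selectPredictors(data.frame(variable = "x", p = 0.1)), "x")
  expect_length(selectPredictors(data.frame(variable = "x", p = 0.11)), 0L)
  expect_length(selectPredictors(data.frame(variable = "x", p = NA_real_)),
                0L)
})

test_that("a single binary predictor gives the cross-product odds ratio", {
  set.seed(8)
  sim <- simulateCarrierPhenotypes(400, betas = c(familyHistory = log(6)))
  fit <- logisticFit(sim$phenotypes, sim$carriers, "familyHistory")
  ph <- sim$phenotypes
  carrier <- ph$sample %in% sim$carriers
  fh <- ph$familyHistory == "yes"
  orHand <- (sum(carrier & fh) * sum(!carrier & !fh)) /
    (sum(carrier & !fh) * sum(!carrier & fh))
  expect_equal(fit$coefficients$or, orHand, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(fit$coefficients$ciLow < fit$coefficients$or &&
                fit$coefficients$or < fit$coefficients$ciHigh)
})

test_that("Nagelkerke R2 is ~0 under the null and invariant to rescaling", {
  set.seed(12)
  sim <- simulateCarrierPhenotypes(800, betas = c(familyHistory = 0),
                                   intercept = -1)
  fit <- logisticFit(sim$phenotypes, sim$carriers, "familyHistory")
  expect_lt(fit$nagelkerkeR2, 0.02)
  expect_gte(fit$nagelkerkeR2, 0)
  # rescaling a continuous predictor leaves R2 unchanged
  sim2 <- simulateCarrierPhenotypes(500, betas = c(familyHistory = log(4)))
  f1 <- logisticFit(sim2$phenotypes, sim2$carriers,
                    c("familyHistory", "durationFromOnset"))
  ph <- sim2$phenotypes
  ph$durationFromOnset <- ph$durationFromOnset / 100
  f2 <- logisticFit(ph, sim2$carriers, c("familyHistory",
                                         "durationFromOnset"))
  expect_equal(f1$nagelkerkeR2, f2$nagelkerkeR2, tolerance = 1e-6)
})

test_that("onset age enters the model grouped by decade", {
  set.seed(5)
  sim <- simulateCarrierPhenotypes(300)
  fit <- logisticFit(sim$phenotypes, sim$carriers,
                     c("ageOnset", "familyHistory"))
  expect_setequal(fit$coefficients$predictor, c("ageOnset", "familyHistory"))
  # refit by hand on the decade index to confirm the encoding
  d <- data.frame(
    outcome = as.integer(sim$phenotypes$sample %in% sim$carriers),
    dec = floor(sim$phenotypes$ageOnset / 10),
    fh = as.integer(sim$phenotypes$familyHistory == "yes"))
  hand <- glm(outcome ~ dec + fh, data = d, family = binomial())
  expect_equal(fit$coefficients$beta[fit$coefficients$predictor == "ageOnset"],
               unname(coef(hand)["dec"]), tolerance = 1e-8)
})

test_that("complete separation is flagged, not silently reported", {
  ph <- simulateCarrierPhenotypes(80)$phenotypes
  carriers <- ph$sample[ph$familyHistory == "yes"]
  if (length(carriers) >= 2 && length(carriers) <= 78) {
    fit <- logisticFit(ph, carriers, "familyHistory")
    expect_true(fit$separation)
  }
})

test_that("KM estimates equal the empirical survival function without censoring", {
  times <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km <- kmLogrank(c(times, times + 2), rep(1, 16),
                  rep(c("a", "b"), each = 8))
  ta <- km$table[km$table$group == "a", ]
  emp <- vapply(ta$time, function(t) mean(times > t), numeric(1))
  expect_equal(ta$estimate, emp)
  # one group, all distinct times: step heights 1/n remaining
  expect_error(kmLogrank(times, rep(1, 8), rep("a", 8)), "group")
})

test_that("log-rank is null on identical groups and powered under 2x hazard", {
  set.seed(14)
  same <- rep(c(10, 20, 30, 40), 10)
  km <- kmLogrank(c(same, same), rep(1, 80), rep(c("x", "y"), each = 40))
  expect_gte(km$p, 0.99)
  rejections <- vapply(1:120, function(i) {
    t1 <- rexp(200, 1)
    t2 <- rexp(200, 2)
    kmLogrank(c(t1, t2), rep(1, 400), rep(c("g1", "g2"), each = 200))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

test_that("logistic coefficient recovery and CI coverage at known truth", {
  # cohort-sized calibration: beta = log 10 on family history, 200 seeds;
  # recovery is checked on the log-odds scale where the MLE is near-unbiased
  truth <- log(10)
  est <- matrix(NA_real_, 200, 3)
  for (s in 1:200) {
    set.seed(6000 + s)
    sim <- simulateCarrierPhenotypes(431, betas = c(familyHistory = truth),
                                     intercept = -2)
    fit <- logisticFit(sim$phenotypes, sim$carriers, "familyHistory")
    est[s, ] <- c(fit$coefficients$beta, fit$coefficients$ciLow,
                  fit$coefficients$ciHigh)
  }
  expect_lt(abs(mean(est[, 1]) - truth) / truth, 0.10)
  coverage <- mean(est[, 2] <= exp(truth) & exp(truth) <= est[, 3])
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.98)
})
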