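#' Collinearity screen of clinical variables
#'
#' Pearson correlations between age of onset and age at diagnosis, and
#' between duration from onset and duration from diagnosis. Diagnosis-
#' related variables and the derived time-to-diagnosis are flagged for
#' exclusion from association testing: disease onset is the biologically
#' meaningful anchor, while diagnosis timing reflects clinical services.
#'
#' @param phenotypes data.frame with `ageOnset`, `ageDiagnosis`,
#'   `durationFromOnset`, `durationFromDiagnosis`.
#' @return List: `correlations` (data.frame pair, r, n) and
#'   `excludedVariables`.
#' @export
collinearityScreen <- function(phenotypes) {
  pairCor <- function(x, y, label) {
    ok <- stats::complete.cases(phenotypes[[x]], phenotypes[[y]])
    r <- if (sum(ok) >= 3)
      stats::cor(phenotypes[[x]][ok], phenotypes[[y]][ok]) else NA_real_
    data.frame(pair = label, r = r, n = sum(ok), stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    pairCor("ageOnset", "ageDiagnosis", "onset_vs_diagnosis_age"),
    pairCor("durationFromOnset", "durationFromDiagnosis",
            "duration_onset_vs_diagnosis"))
  list(correlations = correlations,
       excludedVariables = c("ageDiagnosis", "durationFromDiagnosis",
                             "timeToDiagnosis"))
}

.completeBinary <- function(x, known) {
  out <- as.character(x)
  out[!out %in% known] <- NA
  out
}

#' Univariate genotype-phenotype tests
#'
#' Compares carriers of a genotype group against all other cases on the
#' five analysis variables. Categorical variables (sex, site of onset,
#' family history) use the two-tailed Fisher exact kernel
#' ([fisherTwoTailed()]); age of onset uses a two-sample t-test (pooled
#' variance by default); duration from onset uses the Mann-Whitney U test.
#' Rows with an unknown value are dropped per variable (complete-case).
#'
#' @param phenotypes case phenotype data.frame (see [simulateCohort()]).
#' @param carriers character vector of carrier sample ids defining the
#'   group; all other rows are the comparison group.
#' @param welch use Welch's t-test instead of pooled variance.
#' @return data.frame: variable, test, statistic, effect, nGroup, nOther, p.
#' @export
univariateTests <- function(phenotypes, carriers, welch = FALSE) {
  grp <- phenotypes$sample %in% carriers
  if (!any(grp) || all(grp))
    stop("carrier group must be a non-empty strict subset of cases",
         call. = FALSE)

  catTest <- function(values, positive, variable) {
    ok <- !is.na(values)
    g <- grp[ok]; v <- values[ok] == positive
    a <- sum(g & v); b <- sum(g & !v); c <- sum(!g & v); d <- sum(!g & !v)
    data.frame(variable = variable, test = "fisher_two_tailed",
               statistic = NA_real_,
               effect = a / (a + b) - c / (c + d),
               nGroup = a + b, nOther = c + d,
               p = fisherTwoTailed(a, b, c, d), stringsAsFactors = FALSE)
  }
  numTest <- function(values, variable, kind) {
    ok <- !is.na(values)
    x <- values[ok & grp]; y <- values[ok & !grp]
    if (kind == "t") {
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(data.frame(variable = variable, test = "t_test",
                          statistic = NA_real_, effect = mean(x) - mean(y),
                          nGroup = length(x), nOther = length(y),
                          p = NA_real_, stringsAsFactors = FALSE))
      tt <- stats::t.test(x, y, var.equal = !welch)
      data.frame(variable = variable, test = "t_test",
                 statistic = unname(tt$statistic),
                 effect = mean(x) - mean(y),
                 nGroup = length(x), nOther = length(y),
                 p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      exact <- min(length(x), length(y)) < 30 &&
        !any(duplicated(c(x, y)))
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = TRUE))
      data.frame(variable = variable, test = "mann_whitney_u",
                 statistic = unname(wt$statistic),
                 effect = stats::median(x) - stats::median(y),
                 nGroup = length(x), nOther = length(y),
                 p = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  rbind(
    catTest(.completeBinary(phenotypes$sex, c("female", "male")), "female",
            "sex"),
    numTest(phenotypes$ageOnset, "ageOnset", "t"),
    numTest(phenotypes$durationFromOnset, "durationFromOnset", "u"),
    catTest(.completeBinary(phenotypes$siteOfOnset, c("bulbar", "spinal")),
            "bulbar", "siteOfOnset"),
    catTest(.completeBinary(phenotypes$familyHistory, c("yes", "no")), "yes",
            "familyHistory"))
}

#' Select predictors for logistic modelling
#'
#' Variables with univariate p <= `threshold` (default 0.1, boundary
#' included), in the input order.
#'
#' @param results output of [univariateTests()].
#' @param threshold model-entry p-value threshold.
#' @return Character vector of selected variable names.
#' @export
selectPredictors <- function(results, threshold = 0.1) {
  results$variable[!is.na(results$p) & results$p <= threshold]
}

#' Nagelkerke pseudo-R-squared
#'
#' `(1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))` from the null and fitted
#' log-likelihoods of a binomial model.
#'
#' @param fit a fitted binomial `glm`.
#' @return Numeric in [0, 1].
#' @export
nagelkerkeR2 <- function(fit) {
  n <- stats::nobs(fit)
  ll1 <- as.numeric(stats::logLik(fit))
  y <- fit$y
  p0 <- mean(y)
  ll0 <- if (p0 %in% c(0, 1)) 0 else
    sum(y * log(p0) + (1 - y) * log(1 - p0))
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

#' Binomial logistic regression for carrier status
#'
#' Fits carrier status against the selected phenotype predictors by maximum
#' likelihood on complete cases. Age of onset enters grouped by decade
#' (`floor(age / 10)`, an ordinal predictor). Reports per-predictor odds
#' ratios with Wald 95% confidence intervals, the Nagelkerke R-squared and
#' a convergence/separation flag; a separated fit is flagged, never
#' silently reported.
#'
#' @param phenotypes case phenotype data.frame.
#' @param carriers carrier sample ids (the binary outcome).
#' @param predictors subset of `c("sex", "ageOnset", "durationFromOnset",
#'   "siteOfOnset", "familyHistory")`.
#' @return List: coefficients (data.frame predictor, beta, or, ciLow,
#'   ciHigh, p), nagelkerkeR2, n, converged, separation.
#' @export
logisticFit <- function(phenotypes, carriers, predictors) {
  if (!length(predictors)) stop("no predictors selected", call. = FALSE)
  d <- data.frame(outcome = as.integer(phenotypes$sample %in% carriers))
  for (p in predictors) {
    d[[p]] <- switch(p,
      sex = ifelse(.completeBinary(phenotypes$sex,
                                   c("female", "male")) == "female", 1L, 0L),
      ageOnset = floor(phenotypes$ageOnset / 10),
      durationFromOnset = phenotypes$durationFromOnset,
      siteOfOnset = ifelse(.completeBinary(phenotypes$siteOfOnset,
                                           c("bulbar", "spinal")) == "bulbar",
                           1L, 0L),
      familyHistory = ifelse(.completeBinary(phenotypes$familyHistory,
                                             c("yes", "no")) == "yes", 1L, 0L),
      stop("unknown predictor: ", p, call. = FALSE))
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm(outcome ~ ., data = d, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  est <- sm[-1, , drop = FALSE]
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    predictor = rownames(est),
    beta = est[, "Estimate"],
    or = exp(est[, "Estimate"]),
    ciLow = exp(est[, "Estimate"] - z * est[, "Std. Error"]),
    ciHigh = exp(est[, "Estimate"] + z * est[, "Std. Error"]),
    p = est[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  separation <- any(abs(est[, "Estimate"]) > 15) ||
    any(est[, "Std. Error"] > 100)
  list(coefficients = coefs, nagelkerkeR2 = nagelkerkeR2(fit),
       n = nrow(d), converged = fit$converged, separation = separation)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per genotype group and the multi-group
#' log-rank chi-square test, via the survival package. Censored samples
#' contribute their duration to last contact.
#'
#' @param durations survival times (months from onset).
#' @param events 1 = died, 0 = censored.
#' @param groups group label per sample (>= 2 non-empty levels).
#' @return List: fit (survfit), table (time, at-risk, events, estimate,
#'   group), chisq, df, p.
#' @export
kmLogrank <- function(durations, events, groups) {
  groups <- as.factor(as.character(groups))
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("each group must contain at least one subject", call. = FALSE)
  if (any(durations < 0)) stop("durations must be nonnegative", call. = FALSE)
  d <- data.frame(time = durations, status = events, group = groups)
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = d)
  sf <- summary(fit)
  tab <- data.frame(
    group = if (is.null(sf$strata)) levels(groups)[1] else
      sub("^group=", "", as.character(sf$strata)),
    time = sf$time, atRisk = sf$n.risk, events = sf$n.event,
    estimate = sf$surv, stringsAsFactors = FALSE)
  lr <- survival::survdiff(survival::Surv(time, status) ~ group, data = d)
  df <- length(lr$n) - 1
  p <- stats::pchisq(lr$chisq, df, lower.tail = FALSE)
  list(fit = fit, table = tab, chisq = unname(lr$chisq), df = df, p = p)
}

#' Simulate phenotypes with a known carrier-status model
#'
#' Calibration generator for the logistic stage: draws the binary
#' predictors, assigns carrier status from a logistic model with known
#' coefficients, and returns a phenotype table plus the carrier set. Used
#' to verify odds-ratio recovery and confidence-interval coverage.
#'
#' @param n cases.
#' @param betas named coefficients on the linear predictor scale; names
#'   from `c("sex", "familyHistory")` (binary 0/1 encodings, female/yes = 1).
#' @param intercept model intercept.
#' @param predictorProbs named Bernoulli probabilities for the predictors.
#' @return List: phenotypes, carriers, linearPredictor.
#' @export
simulateCarrierPhenotypes <- function(n, betas = c(familyHistory = log(10)),
                                      intercept = -2,
                                      predictorProbs = c(sex = 0.41,
                                                         familyHistory = 0.5)) {
  pheno <- data.frame(
    sample = sprintf("SIM-%04d", seq_len(n)),
    sex = ifelse(stats::runif(n) < predictorProbs[["sex"]],
                 "female", "male"),
    ageOnset = round(.truncNorm(n, 59.5, 12.9, 14, 94), 1),
    durationFromOnset = round(.lnormFromMedianIQR(n, 42, c(25, 73.5)), 1),
    siteOfOnset = ifelse(stats::runif(n) < 0.29, "bulbar", "spinal"),
    familyHistory = ifelse(stats::runif(n) <
                             predictorProbs[["familyHistory"]], "yes", "no"),
    vitalStatus = ifelse(stats::runif(n) < 0.85, "died", "censored"),
    stringsAsFactors = FALSE)
  pheno$ageDiagnosis <- pheno$ageOnset + 1
  pheno$durationFromDiagnosis <- pmax(pheno$durationFromOnset - 12, 0.5)
  lp <- rep(intercept, n)
  for (b in names(betas)) {
    x <- switch(b,
                sex = as.integer(pheno$sex == "female"),
                familyHistory = as.integer(pheno$familyHistory == "yes"),
                stop("unsupported predictor in betas: ", b, call. = FALSE))
    lp <- lp + betas[[b]] * x
  }
  carrier <- stats::runif(n) < stats::plogis(lp)
  list(phenotypes = pheno, carriers = pheno$sample[carrier],
       linearPredictor = lp)
}
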