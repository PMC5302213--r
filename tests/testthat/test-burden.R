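test_that("one-tailed kernel reproduces printed carrier-table statistics", {
  expect_equal(round(fisherOneTailed(3, 428, 0, 389), 3), 0.145)
  expect_equal(round(fisherOneTailed(6, 425, 1, 388), 3), 0.080)
  expect_equal(fisherOneTailed(31, 400, 2, 387), 1.761e-7, tolerance = 1e-3)
  expect_identical(fisherOneTailed(0, 431, 0, 389), 1.0)
  # controls in excess: the observed-direction one-sided p is the lower tail
  expect_equal(round(fisherOneTailed(16, 415, 16, 373,
                                     alternative = "less"), 3), 0.453)
})

test_that("two-tailed kernel uses the sum-of-small-probabilities rule", {
  expect_equal(round(fisherTwoTailed(39, 35, 138, 219), 3), 0.028)
  expect_identical(fisherTwoTailed(5, 5, 5, 5), 1.0)
  expect_lt(fisherTwoTailed(26, 48, 16, 341), 5e-7)
})

test_that("kernels agree with fisher.test and a binomial-coefficient oracle", {
  set.seed(2)
  for (i in 1:40) {
    a <- sample(0:12, 1); b <- sample(1:15, 1)
    c <- sample(0:12, 1); d <- sample(1:15, 1)
    orc <- oracleFisher(a, b, c, d)
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    expect_equal(fisherOneTailed(a, b, c, d), orc$oneGreater)
    expect_equal(fisherOneTailed(a, b, c, d),
                 fisher.test(m, alternative = "greater")$p.value)
    expect_equal(fisherOneTailed(a, b, c, d, "less"), orc$oneLess)
    expect_equal(fisherTwoTailed(a, b, c, d), orc$two)
    expect_equal(fisherTwoTailed(a, b, c, d), fisher.test(m)$p.value)
    # the two-tailed p never undercuts the observed-direction one-tailed p
    expect_gte(fisherTwoTailed(a, b, c, d) + 1e-12,
               min(orc$oneGreater, orc$oneLess))
  }
  expect_error(fisherOneTailed(-1, 2, 3, 4), "nonnegative")
  expect_error(fisherOneTailed(0, 0, 3, 4), "margins")
})

test_that("one-tailed p is monotone in case-carrier excess", {
  ps <- vapply(0:6, function(a) fisherOneTailed(a, 20 - a, 3, 17),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # symmetric tables are invariant to label permutation
  expect_equal(fisherTwoTailed(4, 16, 4, 16), fisherTwoTailed(4, 16, 4, 16))
  expect_equal(fisherTwoTailed(4, 16, 7, 13), fisherTwoTailed(7, 13, 4, 16))
})

test_that("ExAC effective-N and carrier integerization follow the stated conventions", {
  expect_identical(exacEffectiveN(60706, 1.0), 60706L)
  expect_identical(exacEffectiveN(60706, 0.5), 30353L)
  expect_identical(exacEffectiveN(1000, 0.333), 333L)
  expect_error(exacEffectiveN(1000, 0), "fraction")
  expect_identical(exacCarrierCount(0.0003, 41848), 12L)
  expect_identical(exacCarrierCount(0.003, 30298), 90L)
  expect_identical(exacCarrierCount(0, 41848), 0L)
})

test_that("reference-population burden reproduces the printed comparisons", {
  nek1 <- burdenVsExac(3, 431, list(total_n = 60706,
                                    fraction_30x = 30298 / 60706,
                                    frequency = 0.003))
  expect_identical(nek1$refCarriers, 90L)
  expect_equal(round(nek1$p, 3), 0.143)
  tbk1 <- burdenVsExac(3, 431, list(total_n = 60706,
                                    fraction_30x = 41848 / 60706,
                                    frequency = 0.0003))
  expect_identical(tbk1$refCarriers, 12L)
  expect_equal(tbk1$p, 4.370e-4, tolerance = 0.10)
  none <- burdenVsExac(0, 431, list(total_n = 60706, fraction_30x = 0.5,
                                    frequency = 0.001))
  expect_gte(none$p, 0.99)
})

test_that("carrier tables count each sample once per gene and panel-wide", {
  classified <- data.frame(
    sample = c("C1", "C1", "C2", "C3", "K1"),
    gene = c("SOD1", "SOD1", "SOD1", "TBK1", "SOD1"),
    variantId = c("v1", "v2", "v1", "v3", "v1"),
    tier = c("pathogenic", "pathogenic", "pathogenic", "loss-of-function",
             "pathogenic"))
  tab <- buildCarrierTable(classified, c("pathogenic", "loss-of-function"),
                           caseIds = c("C1", "C2", "C3", "C4"),
                           controlIds = c("K1", "K2"))
  sod1 <- tab[tab$gene == "SOD1", ]
  expect_identical(sod1$caseCarriers, 2L)  # C1 counted once
  panel <- tab[tab$gene == "PANEL", ]
  expect_identical(panel$caseCarriers, 3L)
  expect_identical(panel$controlCarriers, 1L)
  expect_identical(panel$caseCarriers + panel$caseNonCarriers, 4L)
  expect_error(buildCarrierTable(classified, character(), "C1", "K1"),
               "non-empty")
})

test_that("a TBK1 loss-of-function fixture reproduces 3/431 vs 0/389", {
  classified <- data.frame(sample = c("C1", "C2", "C3"), gene = "TBK1",
                           variantId = c("v1", "v2", "v2"),
                           tier = "loss-of-function")
  tab <- buildCarrierTable(classified, "loss-of-function",
                           caseIds = sprintf("C%d", 1:431),
                           controlIds = sprintf("K%d", 1:389))
  row <- tab[tab$gene == "TBK1", ]
  expect_identical(unlist(row[, -1], use.names = FALSE),
                   c(3L, 428L, 0L, 389L))
  expect_equal(round(burdenTest(tab)$p[tab$gene == "TBK1"], 3), 0.145)
})

test_that("carrier union counts overlapping samples once", {
  expect_identical(carrierUnion(sprintf("P%02d", 1:31),
                                c(sprintf("C9_%02d", 1:43), "P05"))$n, 74L)
  expect_identical(carrierUnion(letters[1:10], letters[11:15])$n, 15L)
  expect_identical(carrierUnion(letters[1:5], letters[1:5])$n, 5L)
  u <- carrierUnion(letters[1:6], letters[4:9])
  expect_lte(u$n, 12L)
})

test_that("multi-variant samples are enumerated with digenic flags", {
  # mirrors the published two-variant carriers: 5 cases + 1 control,
  # two digenic cases, one via C9orf72 + TBK1 frameshift
  classified <- data.frame(
    sample = c("MND-0040", "MND-0040", "MND-0434", "MND-0158", "MND-0211",
               "MND-0119", "MND-0119", "CONTROL-0325", "CONTROL-0325",
               "MND-0001"),
    gene = c("OPTN", "TBK1", "TBK1", "TBK1", "NEK1", "TARDBP", "NEK1",
             "OPTN", "OPTN", "SOD1"),
    variantId = paste0("v", 1:10),
    tier = c("pathogenic", "loss-of-function", "loss-of-function",
             "likely pathogenic", "likely pathogenic", "pathogenic",
             "uncertain significance", "pathogenic", "likely pathogenic",
             "pathogenic"))
  c9 <- c("MND-0434", "MND-0158", "MND-0211")
  multi <- findMultivariantCases(classified, c9)
  expect_identical(nrow(multi), 6L)
  expect_setequal(multi$sample[multi$digenic], c("MND-0040", "MND-0434"))
  expect_identical(multi$nVariants[multi$sample == "MND-0434"], 2L)
  # all single-variant carriers: empty enumeration
  single <- findMultivariantCases(classified[c(4, 10), ], character())
  expect_identical(nrow(single), 0L)
})

test_that("pipeline carrier tables equal the truth ledger exactly", {
  res <- fullPipeline()
  led <- truthLedger(fullCohort())
  ret <- led$variants[led$variants$intendedFate == "retained", ]
  for (nm in names(defaultTierSets())) {
    tset <- defaultTierSets()[[nm]]
    truthCarriers <- unique(ret$sample[ret$intendedTier %in% tset])
    pan <- res$carrierTables[[nm]]
    pan <- pan[pan$gene == "PANEL", ]
    expect_identical(pan$caseCarriers,
                     sum(res$caseIds %in% truthCarriers))
    expect_identical(pan$controlCarriers,
                     sum(res$controlIds %in% truthCarriers))
  }
})
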