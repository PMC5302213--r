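mixedAnnotations <- function() {
  rbind(annRow("missense", variantId = "V1"),
        annRow("stop-gain", variantId = "V2"),
        annRow("synonymous", variantId = "V3"),
        annRow("intronic", variantId = "V4"),
        annRow("intronic", variantId = "V5"),
        annRow("frameshift", variantId = "V6"))
}

test_that("consequence filter keeps the four qualifying classes only", {
  res <- filterConsequence(mixedAnnotations())
  expect_setequal(res$retained$variantId, c("V1", "V2", "V6"))
  expect_identical(nrow(res$retained) + nrow(res$removed), 6L)
  expect_true(all(res$removed$reason == "consequence_excluded"))
  bad <- annRow("nonsense_label")
  expect_error(filterConsequence(bad), "unknown consequence")
})

test_that("population-frequency thresholds are strict", {
  ann <- rbind(annRow(variantId = "A", freqExac = 0.011),
               annRow(variantId = "B", freq1000g = 0.01),
               annRow(variantId = "C", freq1000g = NA, freqExac = NA))
  res <- filterPopulationFrequency(ann)
  expect_identical(res$removed$variantId, "A")
  expect_setequal(res$retained$variantId, c("B", "C"))  # 0.01 and missing kept
})

test_that("the in-cohort rule counts carriers over genotyped samples", {
  ann <- annRow(variantId = "V1")
  calls <- data.frame(sample = sprintf("S%02d", 1:26), variantId = "V1")
  # 26 carriers of 431 = 6.0% > 5%
  res <- filterPopulationFrequency(ann, calls, nSamples = 431)
  expect_identical(res$removed$variantId, "V1")
  expect_identical(res$removed$reason, "cohort_frequency")
  # 21/431 = 4.9% retained
  res2 <- filterPopulationFrequency(ann, calls[1:21, ], nSamples = 431)
  expect_identical(nrow(res2$removed), 0L)
})

test_that("call quality requires depth >= 50 and allele balance >= 0.3", {
  calls <- data.frame(sample = c("a", "b", "c"),
                      depth = c(49, 50, 500),
                      alleleBalance = c(0.5, 0.30, 0.29))
  res <- filterCallQuality(calls)
  expect_identical(res$retained$sample, "b")
  expect_setequal(res$removed$reason, c("low_depth", "low_allele_balance"))
  expect_error(filterCallQuality(data.frame(depth = NA, alleleBalance = 0.4)),
               "must be present")
})

test_that("region exclusion removes inclusive-interval hits with reasons", {
  calls <- data.frame(sample = "s", chrom = c("21", "21", "21", "1"),
                      pos = c(100, 150, 151, 100))
  excl <- data.frame(chrom = "21", start = 100, end = 150, label = "ex1")
  res <- excludeRegions(calls, excl)
  expect_identical(res$retained$pos, c(151, 100))
  expect_true(all(res$removed$reason == "excluded_region:ex1"))
  idty <- excludeRegions(calls, excl[0, ])
  expect_identical(idty$retained, calls)
  expect_error(excludeRegions(calls,
                              data.frame(chrom = "21", start = 5, end = 1,
                                         label = "bad")), "malformed")
})

test_that("BED conversion shifts starts to 1-based inclusive", {
  bed <- data.frame(chrom = "21", start = 99L, end = 150L, name = "ex1")
  reg <- bedToRegions(bed)
  expect_identical(reg$start, 100L)
  expect_identical(reg$end, 150L)
})

test_that("the four filters commute", {
  co <- simulateCohort(smallConfig(seed = 31))
  calls <- variantCalls(co)
  ann <- variantAnnotations(co)
  n <- length(unique(calls$sample))
  ref <- applyVariantFilters(calls, ann, nSamples = n)

  # apply in a different order by hand: region, quality, frequency, consequence
  r1 <- excludeRegions(calls, sod1Exon1Region())$retained
  r2 <- filterCallQuality(r1)$retained
  fr <- filterPopulationFrequency(ann, calls, n)$retained
  cq <- filterConsequence(fr)$retained
  manual <- r2[r2$variantId %in% cq$variantId, ]
  expect_setequal(paste(ref$calls$sample, ref$calls$variantId),
                  paste(manual$sample, manual$variantId))
})

test_that("on synthetic cohorts the retained set equals the planted clean set", {
  res <- fullPipeline()
  led <- truthLedger(fullCohort())$variants
  ret <- led[led$intendedFate == "retained", ]
  expect_setequal(paste(res$classified$sample, res$classified$variantId),
                  paste(ret$sample, ret$variantId))
  # every planted removal reason is realized by the matching filter
  removedLedger <- led[led$intendedFate != "retained", ]
  rep <- res$filter$report
  reasonMap <- c(filtered_low_depth = "low_depth",
                 filtered_low_ab = "low_allele_balance",
                 filtered_consequence = "consequence_excluded",
                 filtered_frequency_ref = "reference_frequency",
                 filtered_frequency_cohort = "cohort_frequency",
                 filtered_region = "excluded_region:SOD1_exon1_false_positives")
  for (fate in unique(removedLedger$intendedFate)) {
    ids <- removedLedger$variantId[removedLedger$intendedFate == fate]
    expect_true(all(ids %in% rep$variantId[rep$reason == reasonMap[[fate]]]),
                label = fate)
  }
  # planted SOD1 exon 1 artifacts are all removed by the region filter
  ex1 <- removedLedger[removedLedger$intendedFate == "filtered_region", ]
  expect_gt(nrow(ex1), 0L)
  expect_false(any(ex1$variantId %in% res$classified$variantId))
})

test_that("loosening a threshold never removes a retained variant", {
  co <- simulateCohort(smallConfig(seed = 32))
  calls <- variantCalls(co)
  ann <- variantAnnotations(co)
  n <- length(unique(calls$sample))
  tight <- applyVariantFilters(calls, ann, nSamples = n)
  loose <- applyVariantFilters(calls, ann, nSamples = n,
                               refThreshold = 0.05, cohortThreshold = 0.2,
                               minDepth = 20, minAB = 0.1)
  expect_true(all(paste(tight$calls$sample, tight$calls$variantId) %in%
                    paste(loose$calls$sample, loose$calls$variantId)))
})
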