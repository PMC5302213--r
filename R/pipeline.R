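#' Tier sets used for burden testing
#'
#' The three qualifying-variant sets reported by the pipeline:
#' loss-of-function only, pathogenic or loss-of-function, and all retained
#' rare variants.
#'
#' @return Named list of tier subsets.
#' @export
defaultTierSets <- function() {
  list(lof = "loss-of-function",
       path_lof = c("pathogenic", "loss-of-function"),
       all = tierLevels())
}

#' Assign survival-analysis genotype groups
#'
#' Mutually exclusive grouping used for the Kaplan-Meier comparison:
#' digenic > C9orf72 expansion > SOD1 pathogenic > other panel gene > nil.
#'
#' @param sampleIds independent case ids.
#' @param pathLofCarriers data.frame of qualifying calls (sample, gene) at
#'   pathogenic/loss-of-function tiers.
#' @param c9Carriers C9orf72 expansion carrier ids.
#' @param digenicSamples ids flagged digenic.
#' @return Character group label per sample.
#' @export
genotypeGroups <- function(sampleIds, pathLofCarriers, c9Carriers,
                           digenicSamples = character()) {
  sod1 <- unique(pathLofCarriers$sample[pathLofCarriers$gene == "SOD1"])
  other <- unique(pathLofCarriers$sample[pathLofCarriers$gene != "SOD1"])
  ifelse(sampleIds %in% digenicSamples, "digenic",
    ifelse(sampleIds %in% c9Carriers, "C9orf72",
      ifelse(sampleIds %in% sod1, "SOD1",
        ifelse(sampleIds %in% other, "other", "nil"))))
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes the stages in order: coverage QC against per-batch negative
#' controls; relatedness pruning to the independent case set; the
#' variant-filter cascade; tiered pathogenicity classification; C9orf72
#' expansion calling; per-gene and panel-wide carrier tables with one-tailed
#' Fisher burden tests; the pathogenic/loss-of-function carrier union;
#' multi-variant (digenic) enumeration; and, when phenotypes are present,
#' the genotype-phenotype stage (univariate screen, p <= 0.1 predictor
#' selection, decade-grouped logistic regression, Kaplan-Meier/log-rank).
#' The in-cohort frequency filter is computed over all QC-passing samples,
#' cases and controls pooled; burden and association use the independent
#' sets. Every stage is deterministic given the input.
#'
#' @param cohort an [MNDCohort-class] (or any object with the same
#'   accessors).
#' @param tierSets named list of tier subsets for burden testing.
#' @param exclusions region exclusions (default SOD1 exon 1).
#' @param ratioThreshold,refThreshold,cohortThreshold,minDepth,minAB,c9Cutoff,entryP
#'   stage thresholds; defaults are the study values (10x, 1%, 5%, 50, 0.3,
#'   100 repeats, 0.1).
#' @param exacRef optional data.frame (gene, total_n, fraction_30x,
#'   frequency) for reference-population burden tests.
#' @return A list with per-stage reports and a `summary` element; see the
#'   package vignette.
#' @export
runPipeline <- function(cohort,
                        tierSets = defaultTierSets(),
                        exclusions = sod1Exon1Region(),
                        ratioThreshold = 10, refThreshold = 0.01,
                        cohortThreshold = 0.05, minDepth = 50, minAB = 0.3,
                        c9Cutoff = 100, entryP = 0.1,
                        exacRef = NULL) {
  si <- sampleInfo(cohort)

  ## stage 1: coverage QC
  qc <- qcFilterSamples(coverageMatrix(cohort), si, ratioThreshold)
  passing <- qc$sample[qc$included]

  ## stage 2: relatedness pruning (cases carry the recruit order)
  kin <- si[!is.na(si$kinshipGroup),
            c("sample", "kinshipGroup", "recruitOrder")]
  names(kin) <- c("sample", "group", "recruitOrder")
  caseIds <- pruneRelated(intersect(passing,
                                    si$sample[si$role == "case"]), kin)
  controlIds <- intersect(passing, si$sample[si$role == "control"])

  ## stage 3: variant filtering (cohort frequency over QC-passing samples)
  callsQC <- variantCalls(cohort)
  callsQC <- callsQC[callsQC$sample %in% passing, , drop = FALSE]
  filt <- applyVariantFilters(callsQC, variantAnnotations(cohort),
                              nSamples = length(passing),
                              exclusions = exclusions,
                              refThreshold = refThreshold,
                              cohortThreshold = cohortThreshold,
                              minDepth = minDepth, minAB = minAB)

  ## stage 4: classification
  classifiedAnn <- classifyVariants(filt$annotations)
  classified <- merge(filt$calls,
                      classifiedAnn[, c("variantId", "tier",
                                        "support_count", "rule_fired")],
                      by = "variantId", sort = FALSE)

  ## stage 5: C9orf72 expansions
  c9 <- c9Status(cohort)
  c9$status <- classifyC9(c9$repeatCount, c9Cutoff)
  c9CaseCarriers <- intersect(
    c9$sample[c9$status == "pathogenic-expansion"], caseIds)

  ## stage 6: carrier tables and burden tests
  carrierTables <- lapply(tierSets, buildCarrierTable,
                          classified = classified,
                          caseIds = caseIds, controlIds = controlIds)
  burden <- lapply(carrierTables, burdenTest)

  exac <- NULL
  if (!is.null(exacRef)) {
    lofTab <- carrierTables[["lof"]]
    exac <- do.call(rbind, lapply(seq_len(nrow(exacRef)), function(i) {
      g <- exacRef$gene[i]
      cc <- lofTab$caseCarriers[lofTab$gene == g]
      res <- burdenVsExac(cc, length(caseIds), exacRef[i, ])
      data.frame(gene = g, caseCarriers = cc, caseN = length(caseIds),
                 effectiveN = res$effectiveN, refCarriers = res$refCarriers,
                 p = res$p, stringsAsFactors = FALSE)
    }))
  }

  ## stage 7: carrier union and multi-variant samples
  qualPathLof <- classified[classified$tier %in%
                              c("pathogenic", "loss-of-function") &
                              classified$sample %in% caseIds, , drop = FALSE]
  union <- carrierUnion(unique(qualPathLof$sample), c9CaseCarriers)
  multi <- findMultivariantCases(
    classified[classified$sample %in% c(caseIds, controlIds), , drop = FALSE],
    c9CaseCarriers)

  ## stage 8: genotype-phenotype association
  genopheno <- NULL
  pheno <- phenotypes(cohort)
  if (!is.null(pheno) && nrow(pheno)) {
    pheno <- pheno[pheno$sample %in% caseIds, , drop = FALSE]
    carriers <- union$samples
    if (length(carriers) && length(carriers) < nrow(pheno)) {
      screen <- collinearityScreen(pheno)
      uni <- univariateTests(pheno, carriers)
      sel <- selectPredictors(uni, entryP)
      fit <- if (length(sel)) logisticFit(pheno, carriers, sel) else NULL
      groups <- genotypeGroups(pheno$sample, qualPathLof, c9CaseCarriers,
                               multi$sample[multi$digenic])
      km <- if (length(unique(groups)) >= 2)
        kmLogrank(pheno$durationFromOnset,
                  as.integer(pheno$vitalStatus == "died"), groups)
      else NULL
      genopheno <- list(collinearity = screen, univariate = uni,
                        selected = sel, logistic = fit,
                        survival = km)
    }
  }

  summary <- list(
    nCasesIndependent = length(caseIds),
    nControls = length(controlIds),
    qcExcluded = sum(!qc$included & qc$role != "negative"),
    nRetainedCalls = nrow(classified),
    panelPathLofCarriers = burden$path_lof[
      burden$path_lof$gene == "PANEL", , drop = FALSE],
    c9Carriers = length(c9CaseCarriers),
    unionCarriers = union$n,
    digenicCases = sum(multi$digenic & multi$sample %in% caseIds)
  )
  list(qc = qc, caseIds = caseIds, controlIds = controlIds,
       filter = filt, classified = classified, classifiedAnnotations =
         classifiedAnn, c9 = c9, carrierTables = carrierTables,
       burden = burden, exac = exac, union = union, multivariant = multi,
       genopheno = genopheno, summary = summary)
}
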