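#' @import methods
NULL

#' Pathogenicity tier levels
#'
#' The five mutually exclusive tiers assigned by [classifyVariants()], ordered
#' from most to least severe: consequence-driven loss-of-function, HGMD-flagged
#' pathogenic, then the three ensemble-vote bands.
#'
#' @return Character vector of the five tier labels.
#' @export
#' @examples
#' tierLevels()
tierLevels <- function() {
  c("loss-of-function", "pathogenic", "likely pathogenic",
    "uncertain significance", "likely benign")
}

#' Genes on the MND panel
#'
#' @return Character vector of the five panel gene symbols.
#' @export
panelGenes <- function() c("SOD1", "TARDBP", "OPTN", "TBK1", "NEK1")

#' Simulation configuration
#'
#' S4 container holding every parameter of the synthetic-cohort generator:
#' cohort and batch sizes, per-gene planted carrier frequencies by tier for
#' cases and controls, the C9orf72 expansion frequency, relatedness structure,
#' phenotype distribution parameters and noise rates. Validity enforces that
#' all probabilities lie in [0, 1] and cohort sizes are positive.
#'
#' @slot nCases,nControls number of sequenced case/control samples
#' @slot batchSize samples per sequencing batch (negative controls extra)
#' @slot negativeControlsPerBatch water blanks per batch (>= 1)
#' @slot carrierFreqCases,carrierFreqControls named list: gene -> named numeric
#'   vector of per-tier carrier probabilities
#' @slot c9ExpansionFreqCases,c9ExpansionFreqControls probability of a
#'   C9orf72 repeat expansion (>= 100 repeats)
#' @slot relatedPairCount number of related case pairs planted
#' @slot qcFailCases,qcFailControls planted coverage-QC failures
#' @slot sexFemaleProb,bulbarProb,famHistProb,deathProb phenotype Bernoulli
#'   parameters
#' @slot onsetMean,onsetSD onset-age normal parameters (years), truncated to
#'   [14, 94]
#' @slot durationMedian,durationIQR disease-duration log-normal parameters
#'   (months): median and c(q25, q75)
#' @slot falseCallRate per-sample probability of an artifact call that the
#'   filter cascade must remove
#' @slot lowDepthRate,lowABRate fraction of planted calls degraded to depth
#'   < 50 / allele balance < 0.3
#' @slot seed integer RNG seed; a fixed seed gives byte-identical output
#' @export
setClass("SimConfig", representation(
  nCases = "integer", nControls = "integer",
  batchSize = "integer", negativeControlsPerBatch = "integer",
  carrierFreqCases = "list", carrierFreqControls = "list",
  c9ExpansionFreqCases = "numeric", c9ExpansionFreqControls = "numeric",
  relatedPairCount = "integer",
  qcFailCases = "integer", qcFailControls = "integer",
  sexFemaleProb = "numeric", onsetMean = "numeric", onsetSD = "numeric",
  durationMedian = "numeric", durationIQR = "numeric",
  bulbarProb = "numeric", famHistProb = "numeric", deathProb = "numeric",
  falseCallRate = "numeric", lowDepthRate = "numeric", lowABRate = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nCases < 1L || object@nControls < 1L)
    msg <- c(msg, "nCases and nControls must be positive")
  if (object@negativeControlsPerBatch < 1L)
    msg <- c(msg, "each batch needs at least one negative control")
  probs <- c(object@c9ExpansionFreqCases, object@c9ExpansionFreqControls,
             object@sexFemaleProb, object@bulbarProb, object@famHistProb,
             object@deathProb, object@falseCallRate, object@lowDepthRate,
             object@lowABRate,
             unlist(object@carrierFreqCases), unlist(object@carrierFreqControls))
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  badTier <- vapply(c(object@carrierFreqCases, object@carrierFreqControls),
                    function(v) !all(names(v) %in% tierLevels()), logical(1))
  if (any(badTier))
    msg <- c(msg, "carrier frequency tiers must be named with tierLevels()")
  if (length(object@durationIQR) != 2L ||
      any(object@durationIQR <= 0) ||
      object@durationIQR[1] >= object@durationIQR[2])
    msg <- c(msg, "durationIQR must be c(q25, q75) with 0 < q25 < q75")
  if (length(msg)) msg else TRUE
})

#' Table 2-style default planted carrier frequencies
#'
#' Per-gene, per-tier carrier probabilities for cases and controls, derived
#' from the observed carrier counts in a Scottish MND panel screen over the
#' analysis denominators (431 independent cases, 389 controls).
#'
#' @param group `"cases"` or `"controls"`.
#' @return Named list gene -> named numeric vector over [tierLevels()].
#' @export
defaultCarrierFrequencies <- function(group = c("cases", "controls")) {
  group <- match.arg(group)
  tiers <- tierLevels()
  mk <- function(counts, n) stats::setNames(counts / n, tiers)
  if (group == "cases") {
    n <- 431
    list(
      SOD1   = mk(c(0, 22, 1, 0, 0), n),
      TARDBP = mk(c(0, 4, 0, 1, 0), n),
      OPTN   = mk(c(0, 1, 2, 1, 0), n),
      TBK1   = mk(c(3, 0, 2, 1, 0), n),
      NEK1   = mk(c(3, 0, 10, 6, 2), n)
    )
  } else {
    n <- 389
    list(
      SOD1   = mk(c(0, 1, 0, 0, 0), n),
      TARDBP = mk(c(0, 0, 0, 0, 0), n),
      OPTN   = mk(c(0, 1, 1, 0, 0), n),
      TBK1   = mk(c(0, 0, 0, 1, 0), n),
      NEK1   = mk(c(0, 0, 8, 4, 4), n)
    )
  }
}

#' Build a simulation configuration
#'
#' Constructor for [SimConfig-class]. Defaults reproduce the study conditions
#' of the Scottish MND panel screen: 440 cases and 400 controls sequenced in
#' batches of 48 with one water blank each, 7 case and 11 control coverage-QC
#' failures and 2 related case pairs (leaving 431 independent cases and 389
#' controls in the analysis set), Table 2-style planted carrier frequencies,
#' a 10.2% C9orf72 expansion frequency in cases, and phenotype distributions
#' matching the cohort summary (41% female; onset 59.5 (SD 12.9) years
#' truncated to 14-94; duration median 42, IQR 25-73.5 months; 29% bulbar
#' onset; 10% family history; 85% deceased).
#'
#' @param nCases,nControls sequenced sample counts.
#' @param batchSize,negativeControlsPerBatch batch structure.
#' @param carrierFreqCases,carrierFreqControls gene -> tier -> probability.
#' @param c9ExpansionFreqCases,c9ExpansionFreqControls expansion probability.
#' @param relatedPairCount related case pairs sharing recruit-order metadata.
#' @param qcFailCases,qcFailControls planted coverage failures.
#' @param sexFemaleProb,onsetMean,onsetSD,durationMedian,durationIQR,bulbarProb,famHistProb,deathProb
#'   phenotype parameters (see [SimConfig-class]).
#' @param falseCallRate,lowDepthRate,lowABRate noise rates.
#' @param seed integer seed.
#' @return A validated `SimConfig`.
#' @export
#' @examples
#' cfg <- simConfig(nCases = 40, nControls = 40, seed = 1)
#' cfg
simConfig <- function(nCases = 440L, nControls = 400L,
                      batchSize = 48L, negativeControlsPerBatch = 1L,
                      carrierFreqCases = defaultCarrierFrequencies("cases"),
                      carrierFreqControls = defaultCarrierFrequencies("controls"),
                      c9ExpansionFreqCases = 44 / 431,
                      c9ExpansionFreqControls = 0,
                      relatedPairCount = 2L,
                      qcFailCases = 7L, qcFailControls = 11L,
                      sexFemaleProb = 0.41,
                      onsetMean = 59.5, onsetSD = 12.9,
                      durationMedian = 42, durationIQR = c(25, 73.5),
                      bulbarProb = 0.29, famHistProb = 0.10,
                      deathProb = 0.85,
                      falseCallRate = 0.02, lowDepthRate = 0.05,
                      lowABRate = 0.05, seed = 1L) {
  new("SimConfig",
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      batchSize = as.integer(batchSize),
      negativeControlsPerBatch = as.integer(negativeControlsPerBatch),
      carrierFreqCases = carrierFreqCases,
      carrierFreqControls = carrierFreqControls,
      c9ExpansionFreqCases = c9ExpansionFreqCases,
      c9ExpansionFreqControls = c9ExpansionFreqControls,
      relatedPairCount = as.integer(relatedPairCount),
      qcFailCases = as.integer(qcFailCases),
      qcFailControls = as.integer(qcFailControls),
      sexFemaleProb = sexFemaleProb, onsetMean = onsetMean, onsetSD = onsetSD,
      durationMedian = durationMedian, durationIQR = durationIQR,
      bulbarProb = bulbarProb, famHistProb = famHistProb,
      deathProb = deathProb,
      falseCallRate = falseCallRate, lowDepthRate = lowDepthRate,
      lowABRate = lowABRate, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nCases, "cases /", object@nControls, "controls,",
      "batches of", object@batchSize, "\n")
  cat("  planted QC failures:", object@qcFailCases, "cases,",
      object@qcFailControls, "controls;",
      object@relatedPairCount, "related pairs\n")
  cat("  C9orf72 expansion freq (cases):",
      signif(object@c9ExpansionFreqCases, 3), "\n")
  cat("  seed:", object@seed, "\n")
})

#' Synthetic MND cohort bundle
#'
#' S4 container for one simulated cohort: the per-sample x per-amplicon
#' coverage matrix, sample metadata (role, batch, recruit order, kinship),
#' per-sample variant calls, the variant annotation table, C9orf72 repeat
#' counts, case phenotypes, and the truth ledger recording what was planted.
#' The ledger is emitted for verification only; no pipeline stage reads it.
#'
#' @slot coverage numeric matrix, samples x amplicons (median per-amplicon
#'   read depth)
#' @slot samples data.frame: sample, role (case/control/negative), batch,
#'   recruitOrder, kinshipGroup
#' @slot calls data.frame of per-sample variant calls (sample, chrom, pos,
#'   ref, alt, gene, depth, alleleBalance)
#' @slot annotations data.frame keyed by variantId with consequence, context
#'   flags, population frequencies, HGMD flag and ten predictor columns
#' @slot c9 data.frame: sample, repeatCount
#' @slot phenotypes data.frame of case clinical records
#' @slot ledger list of data.frames: samples (QC fate), variants (intended
#'   tier and filter fate per planted call)
#' @slot config the generating [SimConfig-class]
#' @export
setClass("MNDCohort", representation(
  coverage = "matrix", samples = "data.frame", calls = "data.frame",
  annotations = "data.frame", c9 = "data.frame", phenotypes = "data.frame",
  ledger = "list", config = "SimConfig"
))

setValidity("MNDCohort", function(object) {
  msg <- character()
  if (!all(rownames(object@coverage) %in% object@samples$sample))
    msg <- c(msg, "coverage rows must be registered samples")
  if (nrow(object@calls) &&
      !all(object@calls$variantId %in% object@annotations$variantId))
    msg <- c(msg, "every call must have an annotation row")
  if (!all(c("samples", "variants") %in% names(object@ledger)))
    msg <- c(msg, "ledger must contain 'samples' and 'variants'")
  if (length(msg)) msg else TRUE
})

#' @describeIn MNDCohort-class coverage matrix accessor
#' @param x,object an `MNDCohort`
#' @export
coverageMatrix <- function(x) x@coverage
#' @describeIn MNDCohort-class sample metadata accessor
#' @export
sampleInfo <- function(x) x@samples
#' @describeIn MNDCohort-class variant call accessor
#' @export
variantCalls <- function(x) x@calls
#' @describeIn MNDCohort-class annotation table accessor
#' @export
variantAnnotations <- function(x) x@annotations
#' @describeIn MNDCohort-class C9orf72 repeat-count accessor
#' @export
c9Status <- function(x) x@c9
#' @describeIn MNDCohort-class case phenotype accessor
#' @export
phenotypes <- function(x) x@phenotypes
#' @describeIn MNDCohort-class truth ledger accessor (verification only)
#' @export
truthLedger <- function(x) x@ledger

setMethod("show", "MNDCohort", function(object) {
  tab <- table(object@samples$role)
  cat("MNDCohort:", sum(tab[c("case", "control")], na.rm = TRUE),
      "samples (", tab[["case"]], "cases,", tab[["control"]], "controls,",
      sum(object@samples$role == "negative"), "negative controls )\n")
  cat("  coverage:", nrow(object@coverage), "x", ncol(object@coverage),
      "amplicons\n")
  cat("  calls:", nrow(object@calls), "across",
      length(unique(object@calls$variantId)), "variants\n")
  cat("  seed:", object@config@seed, "\n")
})
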