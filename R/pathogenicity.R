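#' In-silico predictor support thresholds
#'
#' The ten dbNSFP-style predictors used by the ensemble vote, with the call or
#' score threshold at which each is taken to support pathogenicity or
#' conservation: SIFT = D; PolyPhen-2 HDIV = P or D; LRT = D; MutationTaster
#' = D; MutationAssessor = M or H; FATHMM = D; CADD phred > 15; GERP > 2;
#' phyloP > 2; SiPhy > 10. Continuous thresholds are strict. A missing score
#' never counts as support.
#'
#' @return Named list of predicate functions, one per predictor column; each
#'   maps a vector of scores/calls to a logical support vector (NA -> FALSE).
#' @export
#' @examples
#' predictorThresholds()$cadd_phred(c(15, 15.01, NA))
predictorThresholds <- function() {
  catPred <- function(supporting) {
    force(supporting)
    function(x) !is.na(x) & x %in% supporting
  }
  numPred <- function(cut) {
    force(cut)
    function(x) {
      x <- suppressWarnings(as.numeric(x))
      !is.na(x) & x > cut
    }
  }
  list(
    sift              = catPred("D"),
    polyphen_hdiv     = catPred(c("P", "D")),
    lrt               = catPred("D"),
    mutation_taster   = catPred("D"),
    mutation_assessor = catPred(c("M", "H")),
    fathmm            = catPred("D"),
    cadd_phred        = numPred(15),
    gerp              = numPred(2),
    phylop            = numPred(2),
    siphy             = numPred(10)
  )
}

#' Names of the ten predictor columns
#' @return Character vector of annotation column names.
#' @export
predictorColumns <- function() names(predictorThresholds())

#' Count supporting predictors for missense variants
#'
#' Applies the ten [predictorThresholds()] predicates to each annotation row
#' and counts how many support pathogenicity/conservation. Missing scores
#' count as non-supporting. Defined for missense variants only: the ensemble
#' vote never applies to consequence-classified (loss-of-function) variants.
#'
#' @param annotations data.frame with the [predictorColumns()] and a
#'   `consequence` column.
#' @return Integer vector in `[0, 10]`, one per row.
#' @export
countSupportingPredictors <- function(annotations) {
  if (!all(predictorColumns() %in% names(annotations)))
    stop("annotations must carry the ten predictor columns", call. = FALSE)
  if (!is.null(annotations$consequence) &&
      any(annotations$consequence != "missense"))
    stop("predictor voting applies to missense variants only", call. = FALSE)
  preds <- predictorThresholds()
  support <- vapply(names(preds),
                    function(p) preds[[p]](annotations[[p]]),
                    logical(nrow(annotations)))
  if (nrow(annotations) == 1L) support <- matrix(support, nrow = 1L)
  as.integer(rowSums(support))
}

#' Map an ensemble support count to a tier
#'
#' 7-10 supporting predictors: likely pathogenic; 4-6: uncertain
#' significance; 0-3: likely benign.
#'
#' @param count integer vector in `[0, 10]`.
#' @return Character tier vector.
#' @export
supportCountTier <- function(count) {
  if (any(count < 0L | count > 10L))
    stop("support count must be in [0, 10]", call. = FALSE)
  ifelse(count >= 7L, "likely pathogenic",
         ifelse(count >= 4L, "uncertain significance", "likely benign"))
}

#' Tiered pathogenicity classification
#'
#' Assigns each filtered variant one of the five [tierLevels()] by decision
#' order: (1) stop-gain, frameshift and splice-site variants are
#' loss-of-function on consequence alone, except a stop-gain in the final
#' exon (escapes nonsense-mediated decay) or a splice-site variant predicted
#' to cause in-frame loss of a single exon, both of which are uncertain
#' significance; (2) a missense variant flagged as MND disease-causing in
#' HGMD is pathogenic regardless of scores; (3) remaining missense variants
#' are tiered by the ensemble support count. Classification is a pure
#' function of the annotation row.
#'
#' @param annotations data.frame with columns `consequence`, `final_exon`,
#'   `inframe_exon_skip`, `hgmd_mnd` and the [predictorColumns()]. Only the
#'   four consequence classes that survive filtering are accepted.
#' @return The input with `tier`, `support_count` (NA for non-missense) and
#'   `rule_fired` columns appended.
#' @export
#' @examples
#' ann <- data.frame(consequence = "frameshift", final_exon = FALSE,
#'                   inframe_exon_skip = FALSE, hgmd_mnd = FALSE)
#' ann[predictorColumns()] <- NA
#' classifyVariants(ann)$tier
classifyVariants <- function(annotations) {
  allowed <- c("stop-gain", "frameshift", "splice-site", "missense")
  if (!all(annotations$consequence %in% allowed))
    stop("classification requires filtered variants (consequence one of ",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
  n <- nrow(annotations)
  tier <- character(n)
  rule <- character(n)
  count <- rep(NA_integer_, n)

  cons <- annotations$consequence
  lofClass <- cons %in% c("stop-gain", "frameshift", "splice-site")
  finalExonStop <- cons == "stop-gain" & isTRUE2(annotations$final_exon)
  inframeSkip <- cons == "splice-site" & isTRUE2(annotations$inframe_exon_skip)

  tier[lofClass] <- "loss-of-function"
  rule[lofClass] <- "consequence_lof"
  tier[finalExonStop] <- "uncertain significance"
  rule[finalExonStop] <- "final_exon_stopgain_exception"
  tier[inframeSkip] <- "uncertain significance"
  rule[inframeSkip] <- "inframe_exon_skip_exception"

  mis <- cons == "missense"
  hgmd <- mis & isTRUE2(annotations$hgmd_mnd)
  tier[hgmd] <- "pathogenic"
  rule[hgmd] <- "hgmd_mnd"

  vote <- mis & !hgmd
  if (any(vote)) {
    count[vote] <- countSupportingPredictors(annotations[vote, , drop = FALSE])
    tier[vote] <- supportCountTier(count[vote])
    rule[vote] <- "ensemble_vote"
  }
  annotations$tier <- factor(tier, levels = tierLevels())
  annotations$support_count <- count
  annotations$rule_fired <- rule
  annotations
}

# NA-safe elementwise TRUE test
isTRUE2 <- function(x) !is.na(x) & as.logical(x)

#' Classify C9orf72 repeat counts
#'
#' A hexanucleotide repeat count of at least 100 is a pathogenic expansion.
#'
#' @param repeatCount nonnegative integer vector.
#' @param cutoff expansion threshold (inclusive), default 100.
#' @return Character vector, `"pathogenic-expansion"` or `"no-expansion"`.
#' @export
#' @examples
#' classifyC9(c(2, 99, 100, 800))
classifyC9 <- function(repeatCount, cutoff = 100) {
  if (any(is.na(repeatCount)) || any(repeatCount < 0))
    stop("repeat counts must be nonnegative", call. = FALSE)
  ifelse(repeatCount >= cutoff, "pathogenic-expansion", "no-expansion")
}
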