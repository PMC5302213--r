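#' Consequence-class filter
#'
#' Retains stop-gain, frameshift, splice-site and missense variants;
#' intronic and synonymous variants are excluded. Any other consequence
#' label is an error rather than a silent pass-through.
#'
#' @param annotations data.frame with a `consequence` column.
#' @return List: `retained` (subset of annotations) and `removed` (with a
#'   `reason` column).
#' @export
filterConsequence <- function(annotations) {
  keepClasses <- c("stop-gain", "frameshift", "splice-site", "missense")
  dropClasses <- c("synonymous", "intronic")
  unknown <- setdiff(unique(annotations$consequence),
                     c(keepClasses, dropClasses))
  if (length(unknown))
    stop("unknown consequence label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- annotations$consequence %in% keepClasses
  removed <- annotations[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "consequence_excluded"
  list(retained = annotations[keep, , drop = FALSE], removed = removed)
}

#' In-cohort carrier frequency per variant
#'
#' Distinct carriers of each variant divided by the number of genotyped
#' (QC-passing) samples; carriers, not alleles, are counted.
#'
#' @param calls data.frame with `sample` and `variantId`.
#' @param nSamples genotyped sample count (denominator).
#' @return Named numeric vector, one frequency per variantId.
#' @export
cohortFrequency <- function(calls, nSamples) {
  if (nSamples <= 0) stop("nSamples must be positive", call. = FALSE)
  carriers <- tapply(calls$sample, calls$variantId,
                     function(s) length(unique(s)))
  carriers / nSamples
}

#' Population-frequency filter
#'
#' Removes a variant if its 1000 Genomes frequency or its ExAC frequency is
#' strictly greater than `refThreshold` (1%), or its in-cohort carrier
#' frequency is strictly greater than `cohortThreshold` (5%). A missing
#' reference frequency is treated as 0 (absent from the reference set).
#'
#' @param annotations data.frame with `variantId`, `freq_1000g`, `freq_exac`.
#' @param calls per-sample calls on QC-passing samples (for the in-cohort
#'   frequency); may be NULL to skip the cohort rule.
#' @param nSamples genotyped sample count for the cohort denominator.
#' @param refThreshold,cohortThreshold strict exclusion thresholds.
#' @return List `retained` / `removed` (with `reason`).
#' @export
filterPopulationFrequency <- function(annotations, calls = NULL,
                                      nSamples = NULL,
                                      refThreshold = 0.01,
                                      cohortThreshold = 0.05) {
  f1 <- annotations$freq_1000g
  f2 <- annotations$freq_exac
  f1[is.na(f1)] <- 0
  f2[is.na(f2)] <- 0
  refCommon <- f1 > refThreshold | f2 > refThreshold
  cohortCommon <- rep(FALSE, nrow(annotations))
  if (!is.null(calls) && nrow(calls)) {
    cf <- cohortFrequency(calls, nSamples)
    hit <- annotations$variantId %in% names(cf)[cf > cohortThreshold]
    cohortCommon <- hit
  }
  drop <- refCommon | cohortCommon
  removed <- annotations[drop, , drop = FALSE]
  if (nrow(removed))
    removed$reason <- ifelse(refCommon[drop], "reference_frequency",
                             "cohort_frequency")
  list(retained = annotations[!drop, , drop = FALSE], removed = removed)
}

#' Call-quality filter
#'
#' A per-sample call is retained iff read depth >= `minDepth` (50) and
#' allele balance >= `minAB` (0.3); the exclusion thresholds are strict
#' ("depth < 50 or allele balance < 0.3").
#'
#' @param calls data.frame with `depth` and `alleleBalance`.
#' @param minDepth,minAB retention thresholds.
#' @return List `retained` / `removed` (with `reason`).
#' @export
filterCallQuality <- function(calls, minDepth = 50, minAB = 0.3) {
  if (anyNA(calls$depth) || anyNA(calls$alleleBalance))
    stop("depth and allele balance must be present for every call",
         call. = FALSE)
  lowDepth <- calls$depth < minDepth
  lowAB <- calls$alleleBalance < minAB
  drop <- lowDepth | lowAB
  removed <- calls[drop, , drop = FALSE]
  if (nrow(removed))
    removed$reason <- ifelse(lowDepth[drop], "low_depth", "low_allele_balance")
  list(retained = calls[!drop, , drop = FALSE], removed = removed)
}

#' Region-exclusion filter
#'
#' Removes calls whose position falls inside any excluded interval
#' (1-based, inclusive ends, VCF coordinate convention). A chromosome
#' mismatch is a non-overlap. BED intervals (0-based half-open) must be
#' converted with [bedToRegions()] before use.
#'
#' @param calls data.frame with `chrom` and `pos`.
#' @param exclusions data.frame with `chrom`, `start`, `end`, `label`.
#' @return List `retained` / `removed` (with `reason`).
#' @export
excludeRegions <- function(calls, exclusions) {
  if (is.null(exclusions) || !nrow(exclusions)) {
    removed <- calls[0, , drop = FALSE]
    return(list(retained = calls, removed = removed))
  }
  if (any(exclusions$start > exclusions$end))
    stop("malformed exclusion interval (start > end)", call. = FALSE)
  hitLabel <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(exclusions))) {
    inside <- calls$chrom == exclusions$chrom[i] &
      calls$pos >= exclusions$start[i] & calls$pos <= exclusions$end[i]
    hitLabel[inside & is.na(hitLabel)] <- exclusions$label[i]
  }
  drop <- !is.na(hitLabel)
  removed <- calls[drop, , drop = FALSE]
  if (nrow(removed))
    removed$reason <- paste0("excluded_region:", hitLabel[drop])
  list(retained = calls[!drop, , drop = FALSE], removed = removed)
}

#' Convert BED intervals to 1-based inclusive regions
#'
#' BED is 0-based, half-open; the pipeline's coordinate convention is
#' 1-based with inclusive ends, so start gains 1 and end is unchanged.
#'
#' @param bed data.frame with columns chrom, start, end and optionally name.
#' @return data.frame with chrom, start, end, label (1-based inclusive).
#' @export
bedToRegions <- function(bed) {
  data.frame(chrom = as.character(bed[[1]]), start = bed[[2]] + 1L,
             end = bed[[3]],
             label = if (ncol(bed) >= 4) as.character(bed[[4]]) else "region",
             stringsAsFactors = FALSE)
}

#' Apply the full variant-filter cascade
#'
#' Composes the four filters — consequence, population/cohort frequency,
#' call quality, region exclusion — on a cohort's calls and annotations.
#' The four rules are independent (a call survives iff it passes all four),
#' so the composition is order-free.
#'
#' @param calls per-sample calls from QC-passing samples.
#' @param annotations the variant annotation table.
#' @param nSamples genotyped sample count for the in-cohort frequency.
#' @param exclusions region exclusions, default the SOD1 exon 1 window.
#' @param refThreshold,cohortThreshold,minDepth,minAB thresholds as in the
#'   individual filters.
#' @return List: `calls` (retained, annotated with variantId), `annotations`
#'   (retained variants), `report` (one row per removed call/variant with a
#'   machine-readable reason).
#' @export
applyVariantFilters <- function(calls, annotations, nSamples,
                                exclusions = sod1Exon1Region(),
                                refThreshold = 0.01, cohortThreshold = 0.05,
                                minDepth = 50, minAB = 0.3) {
  cons <- filterConsequence(annotations)
  freq <- filterPopulationFrequency(annotations, calls, nSamples,
                                    refThreshold, cohortThreshold)
  qual <- filterCallQuality(calls, minDepth, minAB)
  regn <- excludeRegions(calls, exclusions)

  keepVariant <- intersect(cons$retained$variantId, freq$retained$variantId)
  keepCallIdx <- rownames(calls) %in%
    intersect(rownames(qual$retained), rownames(regn$retained)) &
    calls$variantId %in% keepVariant
  retained <- calls[keepCallIdx, , drop = FALSE]

  reasonRows <- function(df, idCol) {
    if (!nrow(df)) return(NULL)
    data.frame(level = if (idCol == "variantId" && !"sample" %in% names(df))
                 "variant" else "call",
               sample = if ("sample" %in% names(df)) df$sample else NA,
               variantId = df$variantId, reason = df$reason,
               stringsAsFactors = FALSE)
  }
  report <- rbind(reasonRows(cons$removed, "variantId"),
                  reasonRows(freq$removed, "variantId"),
                  reasonRows(qual$removed, "sample"),
                  reasonRows(regn$removed, "sample"))
  list(calls = retained,
       annotations = annotations[annotations$variantId %in% keepVariant &
                                   annotations$variantId %in%
                                   retained$variantId, , drop = FALSE],
       report = report)
}
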