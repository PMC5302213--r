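#' Panel gene coordinates (GRCh37)
#'
#' Approximate genomic intervals for the five panel genes, used to place
#' simulated variants and to define region exclusions.
#'
#' @return data.frame with gene, chrom, start, end, transcript.
#' @export
panelGeneRegions <- function() {
  data.frame(
    gene = panelGenes(),
    chrom = c("21", "1", "10", "12", "4"),
    start = c(33031935, 11072679, 13142082, 64845840, 170314419),
    end   = c(33041244, 11085549, 13180281, 64891288, 170533780),
    transcript = c("NM_000454", "NM_007375", "NM_001008211", "NM_013254",
                   "NM_012224"),
    stringsAsFactors = FALSE
  )
}

#' SOD1 exon 1 exclusion interval
#'
#' The GC-rich first exon of SOD1 where amplicon sequencing produces
#' recurrent false positives; excluded from analysis by [excludeRegions()].
#'
#' @return One-row data.frame (chrom, start, end, label), 1-based inclusive.
#' @export
sod1Exon1Region <- function() {
  data.frame(chrom = "21", start = 33031935, end = 33032154,
             label = "SOD1_exon1_false_positives", stringsAsFactors = FALSE)
}

#' Generate predictor scores for an intended tier
#'
#' Inverts the ensemble vote: samples a support count uniformly inside the
#' band for the intended tier (7-10 likely pathogenic, 4-6 uncertain, 0-3
#' likely benign; pathogenic intent draws any count, since the HGMD flag
#' overrides the vote), picks which predictors support uniformly at random,
#' and sets continuous scores a fixed margin past or short of their
#' thresholds (CADD 15 +/- 1, GERP 2 +/- 1, phyloP 2 +/- 1, SiPhy 10 +/- 2).
#' Non-supporting predictors are occasionally missing, exercising the
#' missing-as-no-support convention. Loss-of-function is consequence-driven,
#' never score-driven, and is rejected.
#'
#' @param tierIntent one of "pathogenic", "likely pathogenic",
#'   "uncertain significance", "likely benign".
#' @return One-row data.frame with the ten [predictorColumns()] and
#'   `hgmd_mnd` (TRUE iff intent is pathogenic). Uses the global RNG.
#' @export
#' @examples
#' set.seed(1)
#' generatePredictorScores("likely benign")
generatePredictorScores <- function(tierIntent) {
  if (tierIntent == "loss-of-function")
    stop("loss-of-function is consequence-driven, not score-driven",
         call. = FALSE)
  band <- switch(tierIntent,
                 "pathogenic" = 0:10,
                 "likely pathogenic" = 7:10,
                 "uncertain significance" = 4:6,
                 "likely benign" = 0:3,
                 stop("unknown tier intent: ", tierIntent, call. = FALSE))
  k <- if (length(band) == 1L) band else sample(band, 1L)
  supporting <- sample(predictorColumns(), k)
  supVal <- list(sift = "D", polyphen_hdiv = "D", lrt = "D",
                 mutation_taster = "D", mutation_assessor = "H", fathmm = "D",
                 cadd_phred = 16, gerp = 3, phylop = 3, siphy = 12)
  nonVal <- list(sift = "T", polyphen_hdiv = "B", lrt = "N",
                 mutation_taster = "N", mutation_assessor = "N", fathmm = "T",
                 cadd_phred = 14, gerp = 1, phylop = 1, siphy = 8)
  out <- lapply(predictorColumns(), function(p) {
    if (p %in% supporting) supVal[[p]]
    else if (stats::runif(1) < 0.2) NA  # missing score, counts as no support
    else nonVal[[p]]
  })
  names(out) <- predictorColumns()
  out$hgmd_mnd <- tierIntent == "pathogenic"
  as.data.frame(out, stringsAsFactors = FALSE)
}

# duration-style log-normal: meanlog from the median, sdlog from the IQR
.lnormFromMedianIQR <- function(n, med, iqr) {
  sdlog <- log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
}

.truncNorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# coverage row with an exact target median after rounding
.coverageRow <- function(nAmp, targetMedian) {
  row <- stats::rlnorm(nAmp, meanlog = log(targetMedian + 1), sdlog = 0.35)
  row <- row * (targetMedian / stats::median(row))
  round(row)
}

.randBase <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Simulate a synthetic MND case-control cohort
#'
#' Generates a complete cohort bundle with known planted truth: a coverage
#' matrix with per-batch water-blank negative controls and a configured
#' number of coverage-QC failures; per-sample variant calls with annotations
#' whose planted pathogenicity tiers follow the configured per-gene carrier
#' frequencies; call-level noise (low read depth, low allele balance) and
#' artifact variants (synonymous/intronic, common in reference populations,
#' common in the cohort, or inside the SOD1 exon 1 false-positive window)
#' for the filter cascade to remove; C9orf72 repeat counts; case phenotypes;
#' and a truth ledger recording the intended QC fate of every sample and the
#' intended filter fate and tier of every call. Carrier variants are planted
#' on analysis-eligible samples (passing QC, not the pruned member of a
#' related pair), so configured frequencies refer to the analysis
#' denominators. The ledger is for verification only and is never read by
#' the pipeline.
#'
#' @param config a [SimConfig-class], see [simConfig()].
#' @return An [MNDCohort-class].
#' @export
#' @examples
#' cohort <- simulateCohort(simConfig(nCases = 30, nControls = 30, seed = 7,
#'                                    qcFailCases = 1, qcFailControls = 1,
#'                                    relatedPairCount = 1))
#' cohort
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  regions <- panelGeneRegions()
  sod1ex1 <- sod1Exon1Region()

  ## ---- sample sheet and batches ----
  caseIds <- sprintf("MND-%04d", seq_len(config@nCases))
  ctrlIds <- sprintf("CONTROL-%04d", seq_len(config@nControls))
  ids <- c(caseIds, ctrlIds)
  roles <- c(rep("case", config@nCases), rep("control", config@nControls))
  batch <- ceiling(seq_along(ids) / config@batchSize)
  nBatches <- max(batch)
  negIds <- unlist(lapply(seq_len(nBatches), function(b)
    sprintf("NEG-B%02d-%d", b, seq_len(config@negativeControlsPerBatch))))
  negBatch <- rep(seq_len(nBatches), each = config@negativeControlsPerBatch)

  samples <- data.frame(
    sample = c(ids, negIds),
    role = c(roles, rep("negative", length(negIds))),
    batch = c(batch, negBatch),
    recruitOrder = c(seq_len(config@nCases), rep(NA_integer_,
                     config@nControls + length(negIds))),
    kinshipGroup = NA_character_,
    stringsAsFactors = FALSE
  )

  ## related case pairs: consecutive recruits grouped; later recruit pruned
  if (config@relatedPairCount > 0) {
    if (2L * config@relatedPairCount > config@nCases)
      stop("more related pairs than cases", call. = FALSE)
    pairIdx <- sample(config@nCases, 2L * config@relatedPairCount)
    for (i in seq_len(config@relatedPairCount)) {
      members <- caseIds[pairIdx[c(2 * i - 1, 2 * i)]]
      samples$kinshipGroup[samples$sample %in% members] <- sprintf("K%02d", i)
    }
  }
  prunedMember <- unlist(lapply(split(samples, samples$kinshipGroup),
    function(g) g$sample[order(g$recruitOrder)][-1]))

  ## planted QC failures, never on related-pair members
  eligFail <- function(role) {
    ok <- samples$role == role & is.na(samples$kinshipGroup)
    samples$sample[ok]
  }
  qcFail <- c(sample(eligFail("case"), config@qcFailCases),
              sample(eligFail("control"), config@qcFailControls))
  samples$qcIntent <- ifelse(samples$sample %in% qcFail, "fail",
                             ifelse(samples$role == "negative", "negative",
                                    "pass"))
  analysisEligible <- samples$qcIntent == "pass" &
    !(samples$sample %in% prunedMember)
  samples$analysisEligible <- analysisEligible

  ## ---- coverage matrix ----
  nAmp <- 120L
  ampIds <- sprintf("AMP%03d", seq_len(nAmp))
  coverage <- matrix(0, nrow(samples), nAmp,
                     dimnames = list(samples$sample, ampIds))
  for (b in seq_len(nBatches)) {
    inBatch <- samples$batch == b
    negHere <- samples$sample[inBatch & samples$role == "negative"]
    negMedians <- round(stats::runif(length(negHere), 20, 80))
    for (j in seq_along(negHere))
      coverage[negHere[j], ] <- .coverageRow(nAmp, negMedians[j])
    negRef <- stats::median(negMedians)
    for (s in samples$sample[inBatch & samples$role != "negative"]) {
      ratio <- if (samples$qcIntent[samples$sample == s] == "fail")
        stats::runif(1, 0.5, 9.5)
      else
        pmax(stats::rlnorm(1, log(60), 0.4), 10.5)
      coverage[s, ] <- .coverageRow(nAmp, negRef * ratio)
    }
  }

  ## ---- variant catalog + carrier planting ----
  annRows <- list()
  callRows <- list()
  ledgerRows <- list()
  vCounter <- 0L
  newVariantId <- function() {
    vCounter <<- vCounter + 1L
    sprintf("VAR%04d", vCounter)
  }
  makeVariant <- function(gene, tier, consequence, inExon1 = FALSE,
                          freqRef = NULL, hgmdOverride = NULL) {
    r <- regions[regions$gene == gene, ]
    pos <- if (inExon1) sample(sod1ex1$start:sod1ex1$end, 1L)
           else {
             p <- sample(r$start:r$end, 1L)
             if (gene == "SOD1") while (p <= sod1ex1$end) p <- sample(r$start:r$end, 1L)
             p
           }
    ref <- .randBase(1)
    alt <- if (consequence == "frameshift") paste0(ref, .randBase(1)) else {
      a <- .randBase(1); while (a == ref) a <- .randBase(1); a
    }
    if (is.null(freqRef))
      freqRef <- if (stats::runif(1) < 0.5) c(0, 0)
                 else stats::runif(2, 0, 0.008)
    scores <- if (consequence == "missense" && !is.na(tier))
      generatePredictorScores(tier)
    else {
      s <- as.data.frame(as.list(stats::setNames(rep(NA, 10),
                                                 predictorColumns())))
      s$hgmd_mnd <- FALSE
      s
    }
    if (consequence == "missense" && is.na(tier)) {
      scores <- generatePredictorScores("likely benign")
      scores$hgmd_mnd <- FALSE
    }
    if (!is.null(hgmdOverride)) scores$hgmd_mnd <- hgmdOverride
    id <- newVariantId()
    row <- data.frame(variantId = id, chrom = r$chrom, pos = pos, ref = ref,
                      alt = alt, gene = gene, transcript = r$transcript,
                      consequence = consequence,
                      final_exon = FALSE, inframe_exon_skip = FALSE,
                      freq_1000g = freqRef[1], freq_exac = freqRef[2],
                      stringsAsFactors = FALSE)
    cbind(row, scores)
  }

  tiers <- tierLevels()
  lofConsequences <- c("stop-gain", "frameshift", "splice-site")
  eligByRole <- split(samples$sample[analysisEligible],
                      samples$role[analysisEligible])
  for (gene in panelGenes()) {
    for (role in c("case", "control")) {
      freqs <- if (role == "case") config@carrierFreqCases[[gene]]
               else config@carrierFreqControls[[gene]]
      if (is.null(freqs)) next
      elig <- eligByRole[[role]]
      if (is.null(elig)) next
      ## at most one planted variant per (sample, gene): cumulative draw
      u <- stats::runif(length(elig))
      cuts <- cumsum(freqs[tiers])
      cuts[is.na(cuts)] <- 0
      tierPick <- tiers[pmax(findInterval(u, c(0, cuts), left.open = TRUE,
                                          rightmost.closed = FALSE), 1L)]
      carriers <- which(u < cuts[length(cuts)])
      for (tier in tiers) {
        who <- elig[carriers[tierPick[carriers] == tier]]
        if (!length(who)) next
        ## small shared catalog; SOD1 pathogenic dominated by a founder allele
        ncat <- max(1L, ceiling(length(who) * 0.4))
        cons <- if (tier == "loss-of-function")
          sample(lofConsequences, ncat, replace = TRUE)
        else rep("missense", ncat)
        cat <- lapply(seq_len(ncat), function(i)
          makeVariant(gene, tier, cons[i]))
        w <- if (gene == "SOD1" && tier == "pathogenic" && ncat > 1)
          c(0.8, rep(0.2 / (ncat - 1), ncat - 1)) else rep(1 / ncat, ncat)
        pick <- sample.int(ncat, length(who), replace = TRUE, prob = w)
        annRows <- c(annRows, cat)
        for (j in seq_along(who)) {
          v <- cat[[pick[j]]]
          u2 <- stats::runif(2)
          if (u2[1] < config@lowDepthRate) {
            depth <- sample(5:49, 1L); ab <- stats::runif(1, 0.35, 0.65)
            fate <- "filtered_low_depth"
          } else if (u2[2] < config@lowABRate) {
            depth <- sample(80:2000, 1L); ab <- stats::runif(1, 0.05, 0.29)
            fate <- "filtered_low_ab"
          } else {
            depth <- sample(80:2000, 1L); ab <- stats::runif(1, 0.35, 0.65)
            fate <- "retained"
          }
          callRows[[length(callRows) + 1L]] <- data.frame(
            sample = who[j], variantId = v$variantId, chrom = v$chrom,
            pos = v$pos, ref = v$ref, alt = v$alt, gene = gene,
            depth = depth, alleleBalance = round(ab, 3),
            stringsAsFactors = FALSE)
          ledgerRows[[length(ledgerRows) + 1L]] <- data.frame(
            sample = who[j], variantId = v$variantId, gene = gene,
            kind = "carrier", intendedTier = tier, intendedFate = fate,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  ## ---- artifact calls the filter cascade must remove ----
  addArtifactCall <- function(s, v, fate) {
    callRows[[length(callRows) + 1L]] <<- data.frame(
      sample = s, variantId = v$variantId, chrom = v$chrom, pos = v$pos,
      ref = v$ref, alt = v$alt, gene = v$gene,
      depth = sample(80:2000, 1L),
      alleleBalance = round(stats::runif(1, 0.35, 0.65), 3),
      stringsAsFactors = FALSE)
    ledgerRows[[length(ledgerRows) + 1L]] <<- data.frame(
      sample = s, variantId = v$variantId, gene = v$gene, kind = "artifact",
      intendedTier = NA_character_, intendedFate = fate,
      stringsAsFactors = FALSE)
  }
  nonNeg <- samples$sample[samples$role != "negative" & analysisEligible]
  if (config@falseCallRate > 0) {
    hit <- nonNeg[stats::runif(length(nonNeg)) < config@falseCallRate]
    modes <- sample(c("consequence", "reference_freq", "sod1_exon1"),
                    length(hit), replace = TRUE)
    for (j in seq_along(hit)) {
      v <- switch(modes[j],
        consequence = {
          g <- sample(panelGenes(), 1L)
          makeVariant(g, NA, sample(c("synonymous", "intronic"), 1L))
        },
        reference_freq = {
          g <- sample(panelGenes(), 1L)
          makeVariant(g, NA, "missense",
                      freqRef = stats::runif(2, 0.02, 0.2))
        },
        sod1_exon1 = makeVariant("SOD1", NA, "missense", inExon1 = TRUE))
      annRows <- c(annRows, list(v))
      fate <- switch(modes[j],
                     consequence = "filtered_consequence",
                     reference_freq = "filtered_frequency_ref",
                     sod1_exon1 = "filtered_region")
      addArtifactCall(hit[j], v, fate)
    }
    ## one shared artifact above the 5% in-cohort threshold
    shared <- makeVariant(sample(panelGenes(), 1L), NA, "missense")
    annRows <- c(annRows, list(shared))
    who <- sample(nonNeg, max(2L, ceiling(0.08 * length(nonNeg))))
    for (s in who) addArtifactCall(s, shared, "filtered_frequency_cohort")
  }

  annotations <- if (length(annRows)) do.call(rbind, annRows) else
    stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 13 + length(predictorColumns()))),
      c("variantId", "chrom", "pos", "ref", "alt", "gene", "transcript",
        "consequence", "final_exon", "inframe_exon_skip", "freq_1000g",
        "freq_exac", predictorColumns(), "hgmd_mnd"))
  annotations <- annotations[!duplicated(annotations$variantId), , drop = FALSE]
  calls <- if (length(callRows)) do.call(rbind, callRows) else
    data.frame(sample = character(), variantId = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(), depth = integer(),
               alleleBalance = numeric(), stringsAsFactors = FALSE)
  ledgerVariants <- if (length(ledgerRows)) do.call(rbind, ledgerRows) else
    data.frame(sample = character(), variantId = character(),
               gene = character(), kind = character(),
               intendedTier = character(), intendedFate = character(),
               stringsAsFactors = FALSE)
  rownames(annotations) <- rownames(calls) <- rownames(ledgerVariants) <- NULL

  ## ---- C9orf72 repeat counts ----
  c9 <- data.frame(sample = ids,
                   repeatCount = sample(2:30, length(ids), replace = TRUE),
                   stringsAsFactors = FALSE)
  expandProb <- ifelse(roles == "case", config@c9ExpansionFreqCases,
                       config@c9ExpansionFreqControls)
  eligC9 <- ids %in% samples$sample[analysisEligible]
  expand <- stats::runif(length(ids)) < expandProb & eligC9
  c9$repeatCount[expand] <- sample(100:1600, sum(expand), replace = TRUE)

  ## ---- case phenotypes ----
  nC <- config@nCases
  onset <- round(.truncNorm(nC, config@onsetMean, config@onsetSD, 14, 94), 1)
  ttdMonths <- .lnormFromMedianIQR(nC, 12, c(6, 22))
  durOnset <- round(pmax(.lnormFromMedianIQR(nC, config@durationMedian,
                                             config@durationIQR), 1), 1)
  phenotypes <- data.frame(
    sample = caseIds,
    sex = ifelse(stats::runif(nC) < config@sexFemaleProb, "female", "male"),
    ageOnset = onset,
    ageDiagnosis = round(onset + ttdMonths / 12, 1),
    durationFromOnset = durOnset,
    durationFromDiagnosis = round(pmax(durOnset - ttdMonths, 0.5), 1),
    siteOfOnset = ifelse(stats::runif(nC) < 0.002, "unknown",
                         ifelse(stats::runif(nC) < config@bulbarProb,
                                "bulbar", "spinal")),
    familyHistory = ifelse(stats::runif(nC) < 0.009, "unknown",
                           ifelse(stats::runif(nC) < config@famHistProb,
                                  "yes", "no")),
    vitalStatus = ifelse(stats::runif(nC) < config@deathProb, "died",
                         "censored"),
    stringsAsFactors = FALSE
  )

  ledger <- list(
    samples = samples[, c("sample", "role", "batch", "qcIntent",
                          "analysisEligible", "kinshipGroup",
                          "recruitOrder")],
    variants = ledgerVariants
  )
  new("MNDCohort", coverage = coverage,
      samples = samples[, c("sample", "role", "batch", "recruitOrder",
                            "kinshipGroup")],
      calls = calls, annotations = annotations, c9 = c9,
      phenotypes = phenotypes, ledger = ledger, config = config)
}
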