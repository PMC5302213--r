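# shared fixtures: a small fast cohort and one full-size cohort, built once
smallConfig <- function(seed = 3L, ...) {
  simConfig(nCases = 60, nControls = 50, qcFailCases = 2, qcFailControls = 2,
            relatedPairCount = 1, seed = seed, ...)
}

.fixtureEnv <- new.env(parent = emptyenv())

fullCohort <- function() {
  if (is.null(.fixtureEnv$full))
    .fixtureEnv$full <- simulateCohort(simConfig(seed = 20170301L))
  .fixtureEnv$full
}

fullPipeline <- function() {
  if (is.null(.fixtureEnv$fullRes))
    .fixtureEnv$fullRes <- runPipeline(fullCohort())
  .fixtureEnv$fullRes
}

# minimal annotation row with every predictor at a chosen support pattern
annRow <- function(consequence = "missense", support = rep(FALSE, 10),
                   hgmd = FALSE, finalExon = FALSE, inframeSkip = FALSE,
                   gene = "NEK1", freq1000g = 0, freqExac = 0,
                   variantId = "V1") {
  supVal <- list(sift = "D", polyphen_hdiv = "P", lrt = "D",
                 mutation_taster = "D", mutation_assessor = "M", fathmm = "D",
                 cadd_phred = 20, gerp = 4, phylop = 4, siphy = 14)
  nonVal <- list(sift = "T", polyphen_hdiv = "B", lrt = "N",
                 mutation_taster = "N", mutation_assessor = "L", fathmm = "T",
                 cadd_phred = 5, gerp = 0, phylop = 0, siphy = 2)
  ann <- data.frame(variantId = variantId, gene = gene,
                    consequence = consequence, final_exon = finalExon,
                    inframe_exon_skip = inframeSkip,
                    freq_1000g = freq1000g, freq_exac = freqExac,
                    hgmd_mnd = hgmd, stringsAsFactors = FALSE)
  for (i in seq_along(predictorColumns())) {
    p <- predictorColumns()[i]
    ann[[p]] <- if (support[i]) supVal[[p]] else nonVal[[p]]
  }
  ann
}

# independent hypergeometric oracle built from binomial coefficients only
oracleFisher <- function(a, b, c, d) {
  k <- a + b
  m <- a + c
  n <- b + d
  tot <- m + n
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(tot, k)
  probs <- exp(logp)
  pObs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(tot, k))
  list(oneGreater = sum(probs[support >= a]),
       oneLess = sum(probs[support <= a]),
       two = sum(probs[probs <= pObs * (1 + 1e-7)]))
}
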