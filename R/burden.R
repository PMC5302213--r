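.checkTable <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0))
    stop("contingency counts must be nonnegative", call. = FALSE)
  if ((a + b) <= 0 || (c + d) <= 0)
    stop("both group margins must be positive", call. = FALSE)
}

#' One-tailed Fisher exact test on a 2x2 carrier table
#'
#' Exact hypergeometric tail probability for the table
#' `(a, b; c, d)` = (case carriers, case non-carriers; control carriers,
#' control non-carriers) with all margins fixed. The default
#' `alternative = "greater"` gives the upper tail P(X >= a) — the prior
#' hypothesis that cases carry more qualifying variants than controls;
#' `"less"` gives the lower tail, the convention in which a one-sided p is
#' reported in the direction of the observed deviation when controls are in
#' excess.
#'
#' @param a,b,c,d nonnegative counts; rows are groups, columns carrier
#'   status.
#' @param alternative `"greater"` (case excess, default) or `"less"`.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' fisherOneTailed(3, 428, 0, 389)   # 0.145
#' fisherOneTailed(6, 425, 1, 388)   # 0.080
fisherOneTailed <- function(a, b, c, d,
                            alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  .checkTable(a, b, c, d)
  m <- a + c          # total carriers
  n <- b + d          # total non-carriers
  k <- a + b          # cases
  if (alternative == "greater")
    stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  else
    stats::phyper(a, m, n, k, lower.tail = TRUE)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Sum-of-small-probabilities definition: the total probability of all
#' tables with the same margins whose point probability does not exceed
#' that of the observed table (the convention of `stats::fisher.test`).
#'
#' @inheritParams fisherOneTailed
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' fisherTwoTailed(39, 35, 138, 219)  # 0.028
fisherTwoTailed <- function(a, b, c, d) {
  .checkTable(a, b, c, d)
  m <- a + c
  n <- b + d
  k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Depth-adjusted effective ExAC sample size
#'
#' Scales the reference cohort size by the average fraction of individuals
#' covered at 30x across the gene, rounding to the nearest individual.
#'
#' @param totalIndividuals reference cohort size (ExAC: 60706).
#' @param fractionCovered30x average fraction covered at 30x, in (0, 1].
#' @return Integer effective sample size.
#' @export
#' @examples
#' exacEffectiveN(60706, 0.689)
exacEffectiveN <- function(totalIndividuals, fractionCovered30x) {
  if (fractionCovered30x <= 0 || fractionCovered30x > 1)
    stop("fraction covered must be in (0, 1]", call. = FALSE)
  as.integer(round(totalIndividuals * fractionCovered30x))
}

#' Integer carrier count from a reference frequency
#'
#' Largest integer not exceeding frequency x effective N (floor
#' convention).
#'
#' @param frequency qualifying-variant carrier frequency in [0, 1].
#' @param effectiveN effective individuals.
#' @return Integer carrier count.
#' @export
#' @examples
#' exacCarrierCount(0.003, 30298)   # 90
#' exacCarrierCount(0.0003, 41848)  # 12
exacCarrierCount <- function(frequency, effectiveN) {
  if (frequency < 0 || frequency > 1)
    stop("frequency must be in [0, 1]", call. = FALSE)
  as.integer(floor(frequency * effectiveN))
}

#' Burden test against the depth-adjusted ExAC reference
#'
#' One-tailed Fisher exact test of case carriers against reference carriers,
#' with the reference carrier count derived by [exacCarrierCount()] from the
#' gene's qualifying-variant frequency and depth-adjusted effective N.
#'
#' @param caseCarriers,caseN case carrier count and case cohort size.
#' @param exacRef one-row data.frame (or list) with `total_n`,
#'   `fraction_30x`, `frequency` for the gene.
#' @return List: effectiveN, refCarriers, p.
#' @export
#' @examples
#' burdenVsExac(3, 431, list(total_n = 60706, fraction_30x = 30298 / 60706,
#'                           frequency = 0.003))$p  # 0.143
burdenVsExac <- function(caseCarriers, caseN, exacRef) {
  effN <- exacEffectiveN(exacRef$total_n, exacRef$fraction_30x)
  if (effN <= 0) stop("zero effective reference size", call. = FALSE)
  refCarriers <- exacCarrierCount(exacRef$frequency, effN)
  p <- fisherOneTailed(caseCarriers, caseN - caseCarriers,
                       refCarriers, effN - refCarriers)
  list(effectiveN = effN, refCarriers = refCarriers, p = p)
}

#' Build per-gene and panel-wide carrier tables
#'
#' Counts, for each panel gene and for the panel as a whole, the cases and
#' controls carrying at least one retained variant whose tier lies in
#' `tierSet`. A sample with several qualifying variants — in one gene or in
#' several — is counted once per gene and once panel-wide.
#'
#' @param classified retained calls joined to their tiers: data.frame with
#'   `sample`, `gene`, `tier`.
#' @param tierSet character subset of [tierLevels()] that qualifies.
#' @param caseIds,controlIds the independent analysis sample sets.
#' @return data.frame: gene ("PANEL" for the panel-wide row), caseCarriers,
#'   caseNonCarriers, controlCarriers, controlNonCarriers.
#' @export
buildCarrierTable <- function(classified, tierSet, caseIds, controlIds) {
  if (!length(tierSet)) stop("tierSet must be non-empty", call. = FALSE)
  if (!all(tierSet %in% tierLevels()))
    stop("unknown tier in tierSet", call. = FALSE)
  qual <- classified[classified$tier %in% tierSet &
                       classified$sample %in% c(caseIds, controlIds), ,
                     drop = FALSE]
  count <- function(genes) {
    sub <- qual[qual$gene %in% genes, , drop = FALSE]
    carriers <- unique(sub$sample)
    ca <- sum(caseIds %in% carriers)
    co <- sum(controlIds %in% carriers)
    c(ca, length(caseIds) - ca, co, length(controlIds) - co)
  }
  rows <- lapply(panelGenes(), count)
  rows <- c(rows, list(count(panelGenes())))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("caseCarriers", "caseNonCarriers", "controlCarriers",
                  "controlNonCarriers")
  cbind(data.frame(gene = c(panelGenes(), "PANEL"),
                   stringsAsFactors = FALSE), out)
}

#' Carrier union across the panel and C9orf72
#'
#' Set union of panel pathogenic/loss-of-function carriers and C9orf72
#' expansion carriers; a sample in both is counted once.
#'
#' @param panelCarriers,c9Carriers character vectors of sample ids.
#' @return List: samples (sorted union), n.
#' @export
#' @examples
#' carrierUnion(c("A", "B"), c("B", "C"))$n  # 3
carrierUnion <- function(panelCarriers, c9Carriers) {
  u <- sort(union(panelCarriers, c9Carriers))
  list(samples = u, n = length(u))
}

#' Samples carrying two or more qualifying variants
#'
#' Enumerates samples with at least two retained rare variants across the
#' panel and C9orf72 (an expansion counts as one variant, with tier
#' "pathogenic"), and flags the digenic subset in which at least two of the
#' variants are pathogenic or loss-of-function.
#'
#' @param classified retained calls with `sample`, `gene`, `tier` and
#'   a variant label column `variantId`.
#' @param c9Carriers sample ids with a pathogenic C9orf72 expansion.
#' @return data.frame: sample, nVariants, genes, tiers, digenic.
#' @export
findMultivariantCases <- function(classified, c9Carriers = character()) {
  rows <- classified[, c("sample", "gene", "variantId", "tier")]
  rows$tier <- as.character(rows$tier)
  if (length(c9Carriers))
    rows <- rbind(rows, data.frame(sample = c9Carriers, gene = "C9orf72",
                                   variantId = "C9orf72_HRE",
                                   tier = "pathogenic",
                                   stringsAsFactors = FALSE))
  if (!nrow(rows))
    return(data.frame(sample = character(), nVariants = integer(),
                      genes = character(), tiers = character(),
                      digenic = logical(), stringsAsFactors = FALSE))
  bySample <- split(rows, rows$sample)
  multi <- Filter(function(g) nrow(g) >= 2L, bySample)
  out <- lapply(multi, function(g) {
    g <- g[order(g$gene, g$variantId), ]
    data.frame(sample = g$sample[1], nVariants = nrow(g),
               genes = paste(g$gene, collapse = ";"),
               tiers = paste(g$tier, collapse = ";"),
               digenic = sum(g$tier %in%
                 c("pathogenic", "loss-of-function")) >= 2L,
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(sample = character(), nVariants = integer(),
                      genes = character(), tiers = character(),
                      digenic = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$sample), , drop = FALSE]
}

#' Per-gene and panel burden report
#'
#' Runs the one-tailed Fisher test (case-excess direction) on each row of a
#' carrier table.
#'
#' @param carrierTable output of [buildCarrierTable()].
#' @return The table with a `p` column appended.
#' @export
burdenTest <- function(carrierTable) {
  carrierTable$p <- mapply(fisherOneTailed,
                           carrierTable$caseCarriers,
                           carrierTable$caseNonCarriers,
                           carrierTable$controlCarriers,
                           carrierTable$controlNonCarriers)
  carrierTable
}
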