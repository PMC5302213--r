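#' Median amplicon coverage of one sample
#'
#' Median over the sample's amplicon columns of the coverage matrix; an even
#' number of amplicons takes the mean of the two central values.
#'
#' @param coverage numeric matrix, samples (rows) x amplicons (columns).
#' @param sample row name to summarize.
#' @return Median depth (numeric scalar).
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 40), 1, dimnames = list("S1", NULL))
#' sampleMedianCoverage(m, "S1")  # 25
sampleMedianCoverage <- function(coverage, sample) {
  if (!sample %in% rownames(coverage))
    stop("unknown sample: ", sample, call. = FALSE)
  stats::median(coverage[sample, ])
}

#' Coverage-based sample inclusion
#'
#' Per batch, a sample is included iff its median amplicon coverage strictly
#' exceeds `ratioThreshold` times the median coverage of that batch's
#' negative control (with several negatives, the median of their medians).
#' Negative controls are never part of the analysis set.
#'
#' @param coverage samples x amplicons depth matrix.
#' @param samples data.frame with columns `sample`, `role`
#'   (case/control/negative) and `batch`.
#' @param ratioThreshold required coverage ratio over the blank, default 10.
#' @return data.frame report: sample, role, batch, median, negativeMedian,
#'   ratio, included, reason.
#' @export
qcFilterSamples <- function(coverage, samples, ratioThreshold = 10) {
  stopifnot(all(c("sample", "role", "batch") %in% names(samples)))
  if (!all(samples$sample %in% rownames(coverage)))
    stop("coverage matrix is missing samples", call. = FALSE)
  res <- lapply(split(samples, samples$batch), function(grp) {
    negs <- grp$sample[grp$role == "negative"]
    if (!length(negs))
      stop("batch ", grp$batch[1], " has no negative control", call. = FALSE)
    negMed <- stats::median(vapply(negs, sampleMedianCoverage,
                                   numeric(1), coverage = coverage))
    med <- vapply(grp$sample, sampleMedianCoverage, numeric(1),
                  coverage = coverage)
    ratio <- med / negMed
    isNeg <- grp$role == "negative"
    included <- !isNeg & ratio > ratioThreshold
    reason <- ifelse(isNeg, "negative_control",
                     ifelse(included, "passed_coverage_ratio",
                            "low_coverage_ratio"))
    data.frame(sample = grp$sample, role = grp$role, batch = grp$batch,
               median = unname(med), negativeMedian = negMed,
               ratio = unname(ratio), included = included, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[match(samples$sample, out$sample), , drop = FALSE]
}

#' Prune related samples to an independent set
#'
#' Keeps exactly one member of each kinship group — the earliest recruited —
#' and all singletons. Deterministic and idempotent.
#'
#' @param sampleIds character vector of samples to prune.
#' @param kinship data.frame with columns `sample`, `group`, `recruitOrder`;
#'   samples absent from it are singletons.
#' @return Character vector of retained (independent) sample ids, in the
#'   input order.
#' @export
#' @examples
#' kin <- data.frame(sample = c("A", "B", "C"), group = "K1",
#'                   recruitOrder = c(5, 2, 9))
#' pruneRelated(c("A", "B", "C", "D"), kin)  # B and D
pruneRelated <- function(sampleIds, kinship) {
  if (is.null(kinship) || !nrow(kinship)) return(sampleIds)
  stopifnot(all(c("sample", "group", "recruitOrder") %in% names(kinship)))
  kin <- kinship[kinship$sample %in% sampleIds & !is.na(kinship$group), ,
                 drop = FALSE]
  if (anyDuplicated(kin$sample))
    stop("kinship groups must be disjoint", call. = FALSE)
  drop <- unlist(lapply(split(kin, kin$group), function(g) {
    if (nrow(g) < 2L) return(character())
    if (anyNA(g$recruitOrder))
      stop("missing recruitment order in kinship group ", g$group[1],
           call. = FALSE)
    g$sample[order(g$recruitOrder)][-1]
  }))
  sampleIds[!sampleIds %in% drop]
}
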