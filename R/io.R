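#' Write a cohort bundle to standard formats
#'
#' Emits the cohort as the pipeline's on-disk interchange formats: a
#' multi-sample VCF v4.2 with per-call read depth and allele balance in the
#' genotype fields (`GT:DP:AB`), an annotation TSV (one row per variant),
#' a coverage TSV (samples x amplicons), a phenotype CSV, a C9orf72 repeat
#' CSV, a kinship CSV, and the truth ledger as JSON (verification only).
#'
#' @param cohort an [MNDCohort-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "calls.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    coverage = file.path(dir, "coverage.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    c9 = file.path(dir, "c9orf72.csv"),
    kinship = file.path(dir, "kinship.csv"),
    samples = file.path(dir, "samples.tsv"),
    ledger = file.path(dir, "truth_ledger.json"))

  writeCohortVcf(variantCalls(cohort), variantAnnotations(cohort),
                 sampleIds = sampleInfo(cohort)$sample[
                   sampleInfo(cohort)$role != "negative"],
                 path = paths$vcf)
  utils::write.table(variantAnnotations(cohort), paths$annotations,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- data.frame(sample = rownames(coverageMatrix(cohort)),
                    coverageMatrix(cohort), check.names = FALSE)
  utils::write.table(cov, paths$coverage, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(phenotypes(cohort), paths$phenotypes, row.names = FALSE)
  utils::write.csv(c9Status(cohort), paths$c9, row.names = FALSE)
  si <- sampleInfo(cohort)
  utils::write.csv(si[!is.na(si$kinshipGroup),
                      c("sample", "kinshipGroup", "recruitOrder")],
                   paths$kinship, row.names = FALSE)
  utils::write.table(si, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(truthLedger(cohort), paths$ledger, dataframe = "rows",
                       na = "null", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write per-sample calls as a multi-sample VCF v4.2
#'
#' One row per unique variant; genotype columns carry `GT:DP:AB` for
#' carriers and `0/0:.:.` otherwise. The variant id is written to the ID
#' column and the gene symbol to INFO.
#'
#' @param calls data.frame with sample, variantId, chrom, pos, ref, alt,
#'   gene, depth, alleleBalance.
#' @param annotations annotation table (for variant ordering); optional.
#' @param sampleIds genotype columns to emit, in order.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeCohortVcf <- function(calls, annotations = NULL, sampleIds, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AB,Number=1,Type=Float,Description=",
           "\"Allele balance (alt reads / total reads)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds), collapse = "\t"))
  vars <- unique(calls[, c("variantId", "chrom", "pos", "ref", "alt",
                           "gene")])
  vars <- vars[order(vars$chrom, vars$pos), , drop = FALSE]
  lines <- vapply(seq_len(nrow(vars)), function(i) {
    v <- vars[i, ]
    hit <- calls[calls$variantId == v$variantId, ]
    gt <- rep("0/0:.:.", length(sampleIds))
    idx <- match(hit$sample, sampleIds)
    ok <- !is.na(idx)
    gt[idx[ok]] <- sprintf("0/1:%d:%.3f", hit$depth[ok],
                           hit$alleleBalance[ok])
    paste(c(v$chrom, v$pos, v$variantId, v$ref, v$alt, ".", ".",
            paste0("GENE=", v$gene), "GT:DP:AB", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read per-sample calls from a pipeline VCF
#'
#' Parses a VCF written by [writeCohortVcf()] (or any VCF with `GT:DP:AB`
#' genotype fields) back into the per-sample call table, via vcfR.
#'
#' @param path VCF file.
#' @return data.frame with sample, variantId, chrom, pos, ref, alt, gene,
#'   depth, alleleBalance.
#' @export
readCohortVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gene <- sub("^.*GENE=([^;]+).*$", "\\1", vcfR::getINFO(v))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ab <- vcfR::extract.gt(v, element = "AB", as.numeric = TRUE)
  carrier <- which(!is.na(gt) & gt != "0/0", arr.ind = TRUE)
  data.frame(
    sample = colnames(gt)[carrier[, "col"]],
    variantId = fix$ID[carrier[, "row"]],
    chrom = fix$CHROM[carrier[, "row"]],
    pos = as.integer(fix$POS[carrier[, "row"]]),
    ref = fix$REF[carrier[, "row"]],
    alt = fix$ALT[carrier[, "row"]],
    gene = gene[carrier[, "row"]],
    depth = as.integer(dp[carrier]),
    alleleBalance = ab[carrier],
    stringsAsFactors = FALSE)
}

#' Validate pipeline inputs
#'
#' Report-only schema and sanity checks: required columns present,
#' positions 1-based (>= 1), allele balance inside [0, 1], depths
#' nonnegative, frequencies inside [0, 1], consequence labels known.
#'
#' @param calls,annotations,coverage,samples pipeline inputs (any may be
#'   NULL to skip).
#' @return data.frame of violations (table, row, field, problem); zero rows
#'   when everything is well-formed.
#' @export
validateInputs <- function(calls = NULL, annotations = NULL,
                           coverage = NULL, samples = NULL) {
  bad <- list()
  note <- function(tab, row, field, problem)
    bad[[length(bad) + 1L]] <<- data.frame(
      table = tab, row = row, field = field, problem = problem,
      stringsAsFactors = FALSE)
  needCols <- function(df, cols, tab) {
    miss <- setdiff(cols, names(df))
    for (m in miss) note(tab, NA_integer_, m, "missing column")
    !length(miss)
  }
  if (!is.null(calls) &&
      needCols(calls, c("sample", "variantId", "chrom", "pos", "depth",
                        "alleleBalance"), "calls")) {
    for (i in which(is.na(calls$pos) | calls$pos < 1))
      note("calls", i, "pos", "position must be 1-based (>= 1)")
    for (i in which(is.na(calls$alleleBalance) | calls$alleleBalance < 0 |
                      calls$alleleBalance > 1))
      note("calls", i, "alleleBalance", "allele balance outside [0, 1]")
    for (i in which(is.na(calls$depth) | calls$depth < 0))
      note("calls", i, "depth", "read depth must be nonnegative")
  }
  if (!is.null(annotations) &&
      needCols(annotations, c("variantId", "gene", "consequence",
                              "freq_1000g", "freq_exac"), "annotations")) {
    known <- c("stop-gain", "frameshift", "splice-site", "missense",
               "synonymous", "intronic")
    for (i in which(!annotations$consequence %in% known))
      note("annotations", i, "consequence", "unknown consequence label")
    for (f in c("freq_1000g", "freq_exac"))
      for (i in which(!is.na(annotations[[f]]) &
                        (annotations[[f]] < 0 | annotations[[f]] > 1)))
        note("annotations", i, f, "frequency outside [0, 1]")
  }
  if (!is.null(coverage)) {
    if (any(coverage < 0))
      note("coverage", NA_integer_, "depth", "negative depth")
  }
  if (!is.null(samples) &&
      needCols(samples, c("sample", "role", "batch"), "samples")) {
    for (b in unique(samples$batch))
      if (!any(samples$role[samples$batch == b] == "negative"))
        note("samples", NA_integer_, "batch",
             paste0("batch ", b, " lacks a negative control"))
  }
  if (!length(bad))
    return(data.frame(table = character(), row = integer(),
                      field = character(), problem = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, bad)
}
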