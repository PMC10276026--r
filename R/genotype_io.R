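#' Read a genotype dosage matrix from CSV or VCF
#'
#' The CSV dialect stores individuals as rows and markers as columns, with a
#' header row of marker ids, the first column holding individual ids, and
#' missing calls encoded `NA`. VCF input is restricted to biallelic SNPs;
#' the GT field is converted to ALT-allele dosage (`0/1` -> 1, `./.` ->
#' missing) and multiallelic or unparsable records are skipped with a
#' message.
#'
#' @param path Path to the genotype file.
#' @param dialect `"csv"` or `"vcf"`.
#' @return Numeric matrix (individuals x markers) with entries in
#'   `{0, 1, 2, NA}` and ids as dimnames.
#' @export
read_genotypes <- function(path, dialect = c("csv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("genotype file not found: ", path, call. = FALSE)
  geno <- switch(dialect,
                 csv = .read_genotypes_csv(path),
                 vcf = .read_genotypes_vcf(path))
  if (ncol(geno) == 0L)
    stop("no markers retained from ", path, call. = FALSE)
  geno
}

.read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  geno <- as.matrix(df)
  mode(geno) <- "numeric"
  bad <- !(geno %in% c(0, 1, 2)) & !is.na(geno)
  if (any(bad))
    stop("CSV genotype cells must be 0, 1, 2 or NA; found e.g. ",
         geno[which(bad)[1]], call. = FALSE)
  geno
}

.read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(vcf)
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
  ids <- vcfR::getID(vcf)[biallelic]
  fix <- vcfR::getFIX(vcf)
  fallback <- paste(fix[biallelic, "CHROM"], fix[biallelic, "POS"],
                    sep = "_")
  ids <- ifelse(is.na(ids) | ids == ".", fallback, ids)
  dose <- apply(gt, c(1, 2), .gt_to_dosage)
  unparsable <- rowSums(is.na(gt) != is.na(dose)) > 0
  # a call present in GT but NA after parsing means an allele code we
  # could not interpret; drop such markers rather than guess
  bad_rows <- apply(dose, 1, function(r) FALSE)
  parse_na <- is.na(dose) & !is.na(gt) & gt != "./." & gt != ".|." & gt != "."
  drop_marker <- rowSums(parse_na) > 0
  n_skipped <- n_skipped + sum(drop_marker)
  if (n_skipped > 0)
    message(n_skipped, " VCF record(s) skipped (multiallelic or unparsable)")
  dose <- dose[!drop_marker, , drop = FALSE]
  ids <- ids[!drop_marker]
  out <- t(dose)
  colnames(out) <- ids
  out
}

.gt_to_dosage <- function(gt) {
  if (is.na(gt)) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  suppressWarnings(vals <- as.numeric(alleles))
  if (anyNA(vals) || length(vals) != 2 || any(!vals %in% c(0, 1)))
    return(NA_real_)
  sum(vals)
}

#' Write a genotype matrix in the package CSV dialect
#'
#' @param genotypes Dosage matrix as returned by [read_genotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.csv(as.data.frame(genotypes), path, row.names = TRUE)
  invisible(path)
}

#' Per-marker counted-allele frequency
#'
#' `p_j` is the dosage-counted allele count over twice the number of
#' non-missing individuals at marker `j`. Markers with no calls at all get
#' `NaN` (they are removed by [qc_filter()]).
#'
#' @param genotypes Dosage matrix.
#' @return Named numeric vector of frequencies in `[0, 1]` (or `NaN`).
#' @export
#' @examples
#' g <- matrix(c(0, 1, 2, 2), ncol = 1)
#' allele_frequency(g)  # 5/8
allele_frequency <- function(genotypes) {
  colMeans(genotypes, na.rm = TRUE) / 2
}

#' Marker quality control by call rate and minor allele frequency
#'
#' Keeps markers whose non-missing fraction is at least `call_rate_min` and
#' whose minor allele frequency is at least `maf_min`; both comparisons are
#' inclusive. Defaults are the standard 90% call rate and 5% MAF.
#'
#' @param genotypes Dosage matrix.
#' @param call_rate_min Minimum fraction of non-missing calls, in `[0, 1]`.
#' @param maf_min Minimum minor allele frequency, in `[0, 0.5]`.
#' @return List with the filtered `genotypes` and a `report` of class
#'   `qc_report` holding counts, the percent reduction and the per-marker
#'   call rate and MAF.
#' @export
qc_filter <- function(genotypes, call_rate_min = 0.90, maf_min = 0.05) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  call_rate <- colMeans(!is.na(genotypes))
  p <- allele_frequency(genotypes)
  maf <- pmin(p, 1 - p)
  keep <- call_rate >= call_rate_min & !is.nan(maf) & maf >= maf_min
  n_in <- ncol(genotypes)
  n_out <- sum(keep)
  report <- structure(list(
    n_markers_in = n_in,
    n_markers_out = n_out,
    percent_reduction = 100 * (1 - n_out / n_in),
    thresholds = c(call_rate_min = call_rate_min, maf_min = maf_min),
    markers = data.frame(marker_id = colnames(genotypes),
                         call_rate = unname(call_rate),
                         maf = unname(maf), kept = unname(keep),
                         stringsAsFactors = FALSE)),
    class = "qc_report")
  list(genotypes = genotypes[, keep, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Marker QC: %d -> %d markers (%.2f%% reduction; call rate >= %g, MAF >= %g)\n",
              x$n_markers_in, x$n_markers_out, x$percent_reduction,
              x$thresholds["call_rate_min"], x$thresholds["maf_min"]))
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Each missing cell is replaced by the marker mean dosage `2 p_j`, which
#' leaves the centered coding's column means at zero. Non-missing cells are
#' untouched.
#'
#' @param genotypes Dosage matrix.
#' @param freqs Optional frequencies; recomputed from `genotypes` when
#'   omitted.
#' @return Dosage matrix with no missing entries.
#' @export
impute_missing <- function(genotypes, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequency(genotypes)
  stopifnot(length(freqs) == ncol(genotypes))
  if (any(is.nan(freqs)))
    stop("markers with undefined frequency present; run qc_filter() first",
         call. = FALSE)
  na_idx <- which(is.na(genotypes), arr.ind = TRUE)
  if (nrow(na_idx) > 0)
    genotypes[na_idx] <- 2 * freqs[na_idx[, 2]]
  genotypes
}
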