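#' Genotype quality control
#'
#' Applies the array-QC filters in a fixed, documented order:
#' (1) SNPs whose missing-call fraction exceeds `max_snp_missing` are
#' removed; (2) minor allele frequency is computed on the remaining calls
#' and SNPs with MAF below `min_maf` are removed; (3) samples whose missing
#' fraction over the retained SNPs exceeds `max_sample_missing` are removed.
#' The defaults are the usual array thresholds (5% SNP missingness, 1% MAF,
#' 5% sample missingness). The operation is idempotent.
#'
#' @param panel A [genotype_panel()].
#' @param max_snp_missing Maximum tolerated per-SNP missing fraction.
#' @param min_maf Minimum minor allele frequency (computed from non-missing
#'   calls only); SNPs strictly below are removed.
#' @param max_sample_missing Maximum tolerated per-sample missing fraction.
#' @return List with `panel` (filtered) and `report` (class `qc_report`):
#'   counts removed per filter, thresholds, and input/retained totals.
#' @export
qc_filter <- function(panel, max_snp_missing = 0.05, min_maf = 0.01,
                      max_sample_missing = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  check_prob(max_snp_missing, "max_snp_missing")
  check_prob(min_maf, "min_maf")
  check_prob(max_sample_missing, "max_sample_missing")

  n0 <- length(panel$sample_ids)
  m0 <- length(panel$snp_ids)
  d <- panel$dosage

  snp_miss <- colMeans(is.na(d))
  keep_miss <- snp_miss <= max_snp_missing
  n_removed_missing <- sum(!keep_miss)

  d1 <- d[, keep_miss, drop = FALSE]
  p <- colSums(d1, na.rm = TRUE) / (2 * colSums(!is.na(d1)))
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= min_maf
  n_removed_maf <- sum(!keep_maf)

  keep_snps <- which(keep_miss)[keep_maf]
  d2 <- d[, keep_snps, drop = FALSE]
  if (ncol(d2) == 0) {
    stop("no SNPs left after QC filtering", call. = FALSE)
  }
  samp_miss <- rowMeans(is.na(d2))
  keep_samples <- samp_miss <= max_sample_missing
  n_removed_samples <- sum(!keep_samples)
  if (!any(keep_samples)) {
    stop("no samples left after QC filtering", call. = FALSE)
  }

  out <- subset_panel(panel, samples = which(keep_samples), snps = keep_snps)
  report <- structure(
    list(
      n_snps_removed_missingness = n_removed_missing,
      n_snps_removed_maf = n_removed_maf,
      n_samples_removed_missingness = n_removed_samples,
      thresholds = list(max_snp_missing = max_snp_missing,
                        min_maf = min_maf,
                        max_sample_missing = max_sample_missing),
      n_snps_in = m0, n_snps_out = length(out$snp_ids),
      n_samples_in = n0, n_samples_out = length(out$sample_ids)
    ),
    class = "qc_report"
  )
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    paste0("<qc_report> SNPs %d -> %d (missingness: -%d, MAF: -%d); ",
           "samples %d -> %d (-%d)\n"),
    x$n_snps_in, x$n_snps_out, x$n_snps_removed_missingness,
    x$n_snps_removed_maf, x$n_samples_in, x$n_samples_out,
    x$n_samples_removed_missingness
  ))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
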